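test_that("CLIQUE detection honours the 50 bp gap boundary", {
  # gap exactly 50 -> one clique of 2
  el <- make_elements(c(1000, 1350), c("+", "+"))   # gap = 1350-1300 = 50
  cl <- detect_cliques(el)
  expect_equal(cl$membership, c(1L, 1L))
  expect_equal(cl$cliques$n_members, 2L)
  # gap 51 -> no clique
  el2 <- make_elements(c(1000, 1351), c("+", "+"))
  expect_true(all(is.na(detect_cliques(el2)$membership)))
  # LINE1 participates: Alu-L1-Alu chain with gaps 10 and 10
  el3 <- retro_elements("chr1", c(1000, 1310, 2520),
                        c(1300, 2510, 2820), "+",
                        c("Alu", "LINE1", "Alu"))
  cl3 <- detect_cliques(el3)
  expect_equal(cl3$membership, c(1L, 1L, 1L))
  # unsorted input errors
  el_bad <- el
  el_bad[1:2, ] <- el_bad[2:1, ]
  expect_error(detect_cliques(el_bad), "sorted")
})

test_that("spacer size clamps overlaps and requires one chromosome", {
  a <- data.frame(chrom = "chr1", start = 500, end = 1000)
  b <- data.frame(chrom = "chr1", start = 1100, end = 1400)
  expect_equal(spacer_size(a, b), 100)
  expect_equal(spacer_size(b, a), 100)               # order-free
  expect_equal(spacer_size(a, data.frame(chrom = "chr1", start = 900,
                                         end = 1200)), 0)   # overlap
  expect_equal(spacer_size(a, data.frame(chrom = "chr1", start = 1000,
                                         end = 1300)), 0)   # adjacent
  expect_error(spacer_size(a, data.frame(chrom = "chr2", start = 1100,
                                         end = 1400)), "chromosome")
})

test_that("APSN follows the n+1 intervening-Alu definition", {
  el <- make_elements(c(1000, 2000, 3000, 4000), rep("+", 4))
  p <- enumerate_alu_pairs(el, apsn_max = 110)
  expect_equal(nrow(p), 6L)
  # adjacent pairs have apsn 1; the (1,4) pair has 2 Alus inside -> apsn 3
  expect_equal(p$apsn[p$left == 1 & p$right == 2], 1L)
  expect_equal(p$apsn[p$left == 1 & p$right == 3], 2L)
  expect_equal(p$apsn[p$left == 1 & p$right == 4], 3L)
  # three Alus: pairs with |APSN| 1, 1, 2
  p3 <- enumerate_alu_pairs(make_elements(c(1e3, 2e3, 3e3), rep("+", 3)),
                            apsn_max = 110)
  expect_equal(sort(p3$apsn), c(1L, 1L, 2L))
})

test_that("pair enumeration matches the brute-force midpoint oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    el <- random_landscape(sample(20:60, 1), n_l1 = sample(0:3, 1))
    k <- sample(c(3, 10, 110), 1)
    p <- enumerate_alu_pairs(el, apsn_max = k)
    o <- oracle_pairs(el, apsn_max = k)
    po <- p[order(p$left, p$right)]
    oo <- o[order(o$left, o$right), ]
    expect_equal(po$left, oo$left)
    expect_equal(po$right, oo$right)
    expect_equal(po$apsn, oo$apsn)
    expect_equal(po$spacer_bp, oo$spacer_bp)
    expect_equal(po$inverted, oo$inverted)
  }
})

test_that("interior pair counts follow n*k - k*(k+1)/2", {
  set.seed(2)
  n <- 40; k <- 7
  el <- random_landscape(n)
  p <- enumerate_alu_pairs(el, apsn_max = k)
  expect_equal(nrow(p), n * k - k * (k + 1) / 2)
})

test_that("mirroring the landscape preserves pairs with flipped geometry", {
  set.seed(9)
  el <- random_landscape(40, n_l1 = 2)
  L <- max(el$end) + 1000
  mirrored <- retro_elements(el$chrom, L - el$end, L - el$start,
                             ifelse(el$strand == "+", "-", "+"),
                             el$family, el$subfamily)
  p1 <- enumerate_alu_pairs(el, apsn_max = 10)
  p2 <- enumerate_alu_pairs(mirrored, apsn_max = 10)
  key <- function(p) {
    k <- paste(p$apsn, p$spacer_bp, p$inverted, p$pair_type)
    sort(k)
  }
  expect_equal(key(p1), key(p2))
})

test_that("pair types reflect the four clustering states", {
  # clique A: 2 Alus; clique B: 2 Alus; two singletons
  el <- make_elements(c(1e3, 1.35e3, 5e3, 5.34e3, 2e4, 6e4),
                      rep("+", 6), lengths = 300)
  cl <- detect_cliques(el)
  expect_equal(cl$membership, c(1L, 1L, 2L, 2L, NA, NA))
  p <- enumerate_alu_pairs(el, apsn_max = 110, cliques = cl)
  get_type <- function(i, j) p$pair_type[p$left == i & p$right == j]
  expect_equal(get_type(1, 2), 0L)   # same clique
  expect_equal(get_type(1, 3), 1L)   # different cliques
  expect_equal(get_type(2, 5), 2L)   # hemi-clustered
  expect_equal(get_type(5, 6), 3L)   # non-clustered
  expect_equal(classify_pair_type(c(7L, 7L, 7L, NA), c(7L, 9L, NA, NA)),
               c(0L, 1L, 2L, 3L))
})

test_that("small/small-medium pairs at low APSN carry the tandem flag", {
  el <- make_elements(c(1e3, 2e3, 3e3), "+", lengths = c(100, 200, 300))
  p <- enumerate_alu_pairs(el, apsn_max = 110)
  flag <- function(i, j) p$tandem_flag[p$left == i & p$right == j]
  expect_true(flag(1, 2))     # small-medium
  expect_false(flag(2, 3))    # medium-full
  expect_false(flag(1, 3))    # small-full
})

test_that("pair tables export with genomic coordinates", {
  el <- make_elements(c(1e3, 2e3), c("+", "-"))
  p <- enumerate_alu_pairs(el, apsn_max = 5)
  f <- withr::local_tempfile()
  write_pair_table(p, el, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$left_start, 1000)
  expect_equal(tab$orientation, "inverted")
})
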