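dm <- deletion_size_model()

test_that("single-pair stabilities are the fourth and square roots", {
  s <- fake_surface(values = 0.81)
  # two Alus, one inverted pair with predicted I:D 0.81
  el <- make_elements(c(1000, 2000), c("+", "-"))
  stab <- alu_element_stability(el, s)
  expect_equal(predict(s, enumerate_alu_pairs(el, 10)), 0.81)
  expect_equal(stab$element_stability, rep(0.9, 2), tolerance = 1e-12)
  expect_equal(stab$end_stability, rep(0.81^0.25, 2), tolerance = 1e-12)
  expect_equal(stab$iscore, rep(1 / 0.9, 2), tolerance = 1e-12)
  expect_equal(stab$element_stability, stab$end_stability^2,
               tolerance = 1e-12)
  # two inverted pairs at 0.81 each: element 0.81, iscore ~ 1.23457
  el3 <- make_elements(c(1000, 2000, 3000), c("-", "+", "-"))
  stab3 <- alu_element_stability(el3, s)
  mid <- stab3[2, ]
  expect_equal(mid$element_stability, 0.81, tolerance = 1e-12)
  expect_equal(mid$iscore, 1.2345679, tolerance = 1e-6)
  # no inverted neighbours: fully stable
  el_dir <- make_elements(c(1000, 2000, 3000), "+")
  stab_dir <- alu_element_stability(el_dir, s)
  expect_equal(stab_dir$element_stability, rep(1, 3))
  expect_equal(stab_dir$iscore, rep(1, 3))
})

test_that("an Alu-free landscape scores gene stability 100", {
  g <- gene_model("empty", "chr1", c(5e5, 6e5), c(5.1e5, 6.1e5))
  el <- retro_elements("chr2", 100, 400, "+", "Alu")  # other chromosome
  expect_error(score_gene(g, el, fake_surface(0.8), dm), "chromosome")
  el2 <- retro_elements(c("chr1", "chr2"), c(5e6, 100), c(5e6 + 300, 400),
                        "+", "Alu")   # far outside the landscape
  gs <- score_gene(g, el2, fake_surface(0.8), dm)
  expect_identical(gs$stability, 100)
  expect_identical(gs$gene_rs, 1)
  expect_equal(gs$exons$exon_stability, rep(100, 2))
})

test_that("an all-direct-strand landscape scores 100", {
  set.seed(31)
  el <- random_landscape(60, p_plus = 1)
  g <- gene_model("dir", "chr1", min(el$start) + 1e4,
                  min(el$start) + 1.2e4)
  gs <- score_gene(g, el, fake_surface(0.8), dm)
  expect_equal(gs$stability, 100)
  trk <- landscape_track(g, el, fake_surface(0.8), window_bp = 1e5)
  expect_equal(trk$iscore, rep(1, nrow(trk)))   # flat track at 1.0
})

test_that("a single risk end with known risk and p_deletion composes exactly", {
  s <- fake_surface(values = 0.81)
  # gene with one exon; one inverted Alu pair far to the left, one member
  # close to the exon
  el <- make_elements(c(1000, 2000), c("+", "-"))
  g <- gene_model("g", "chr1", 2500, 2600, flank_bp = 5e4,
                  context_bp = 1e4)
  gs <- score_gene(g, el, s, dm)
  r <- 1 - 0.81^0.25
  ends <- gs$ends
  expect_equal(nrow(ends), 4L)          # two Alus x two ends
  expect_equal(unique(round(ends$risk_end, 12)), round(r, 12))
  manual <- prod(1 - r * p_deletion(dm, c(2500 - 1000, 2500 - 1300,
                                          2500 - 2000, 2500 - 2300)))
  expect_equal(gs$gene_rs, manual, tolerance = 1e-12)
  expect_equal(gs$exons$exon_rs, manual, tolerance = 1e-12)
})

test_that("an exonized Alu contributes (1 - r)^2 through both ends", {
  s <- fake_surface(values = 0.81)
  el <- make_elements(c(10000, 10500), c("+", "-"))
  # second Alu entirely inside the exon: both ends at d_min 0
  g <- gene_model("g", "chr1", 10400, 11000, flank_bp = 5e4,
                  context_bp = 1e4)
  gs <- score_gene(g, el, s, dm)
  r <- 1 - 0.81^0.25
  other <- prod(1 - r * p_deletion(dm, c(10400 - 10000, 10400 - 10300)))
  expect_equal(gs$gene_rs, (1 - r)^2 * other, tolerance = 1e-12)
})

test_that("engine matches the brute-force oracle on random landscapes", {
  set.seed(41)
  s <- fake_surface(values = seq(0.5, 1.1, length.out = 10))
  for (rep in 1:20) {
    el <- random_landscape(sample(10:50, 1), n_l1 = sample(0:2, 1))
    g <- random_gene(sample(1:5, 1), min(el$start), max(el$end),
                     flank = 3e4, context = 1e4)
    gs <- score_gene(g, el, s, dm, apsn_max = 10)
    oracle <- oracle_score_gene(g, el, s, dm, apsn_max = 10)
    expect_equal(gs$gene_rs, oracle$gene_rs, tolerance = 1e-12)
    expect_equal(gs$exons$exon_rs, oracle$exon_rs, tolerance = 1e-12)
    if (length(oracle$end_stability)) {
      expect_equal(sort(unique(round(gs$ends$risk_end, 14))),
                   sort(unique(round(1 - oracle$end_stability, 14))),
                   tolerance = 1e-12)
    }
    # gene stability never exceeds any exon stability
    expect_true(all(gs$gene_rs <= gs$exons$exon_rs + 1e-12))
    expect_gt(gs$gene_rs, 0)
  }
})

test_that("single-exon genes have gene stability equal to exon stability", {
  set.seed(42)
  el <- random_landscape(30)
  g <- random_gene(1, min(el$start), max(el$end), flank = 3e4)
  s <- fake_surface(values = 0.7)
  gs <- score_gene(g, el, s, dm, apsn_max = 10)
  expect_equal(gs$gene_rs, gs$exons$exon_rs, tolerance = 1e-14)
})

test_that("cohort scoring aggregates and records per-gene failures", {
  set.seed(43)
  el <- random_landscape(60)
  g1 <- random_gene(2, min(el$start), max(el$end))
  g1$gene_id <- "A"; g1$group <- "cancer"
  g2 <- random_gene(1, min(el$start), max(el$end))
  g2$gene_id <- "B"; g2$group <- "random"
  g3 <- gene_model("C", "chrX", 100, 200)       # chromosome absent
  rep_ <- score_genes(list(g1, g2, g3), el, fake_surface(0.8), dm,
                      apsn_max = 10)
  expect_equal(nrow(rep_), 2L)
  expect_named(attr(rep_, "errors"), "C")
  expect_true(all(rep_$stability > 0 & rep_$stability <= 100))
  expect_equal(rep_$instability, 100 - rep_$stability)
  expect_equal(rep_$n_exons, c(2L, 1L))
})

test_that("the sensitivity scan matches single-run scores at the default fraction", {
  set.seed(44)
  el <- random_landscape(50)
  genes <- lapply(1:3, function(i) {
    g <- random_gene(sample(1:3, 1), min(el$start), max(el$end))
    g$gene_id <- paste0("g", i)
    g
  })
  s <- fake_surface(values = 0.7)
  scan <- sensitivity_scan(genes, el, s, fracs = c(0.90, 0.95, 0.99),
                           deletion_model = dm, apsn_max = 10)
  base <- score_genes(genes, el, s, dm, apsn_max = 10)
  expect_equal(scan$`frac_0.95`, base$stability, tolerance = 1e-12)
  expect_equal(dim(attr(scan, "ranks")), c(3L, 3L))
})

test_that("genes without near-exon Alus keep their cohort rank across the sweep", {
  # construct three genes whose exons all sit >= 2 kb from any Alu but
  # with different landscape loads, plus one gene with an Alu 5 bp away
  el <- make_elements(seq(0, 99) * 5000 + 1000,
                      rep(c("+", "-"), 50))
  far_gene <- function(id, center, width) {
    gene_model(id, "chr1", center, center + width, flank_bp = 5e4,
               context_bp = 1e4)
  }
  g_far1 <- far_gene("far1", 102500, 1000)    # mid-gap, ~1.2 kb from Alus
  g_far2 <- far_gene("far2", 202500, 1000)
  g_near <- gene_model("near", "chr1", 301305, 302000, flank_bp = 5e4,
                       context_bp = 1e4)       # 5 bp from the Alu at 301000
  s <- fake_surface(values = 0.7)
  scan <- sensitivity_scan(list(g_far1, g_far2, g_near), el, s,
                           fracs = seq(0.90, 0.99, 0.03),
                           deletion_model = dm, apsn_max = 10)
  expect_false(any(is.na(as.matrix(scan[, -1]))))
  # the near-exon gene's trajectory differs in shape from the cohort
  traj <- as.matrix(scan[, -1])
  rel <- traj / traj[, 1]
  expect_gt(max(abs(rel["near" == scan$gene_id, ] -
                    rel["far1" == scan$gene_id, ])), 1e-4)
})

test_that("iScore tracks cover the window and mirror with the landscape", {
  set.seed(46)
  el <- random_landscape(40)
  g <- random_gene(1, min(el$start), max(el$end), flank = 2e4,
                   context = 1e4)
  s <- fake_surface(values = 0.8)
  trk <- landscape_track(g, el, s, window_bp = 5e4, apsn_max = 10)
  span_lo <- min(g$exons$start); span_hi <- max(g$exons$end)
  in_win <- el$family == "Alu" &
    (el$start + el$end) / 2 >= span_lo - 5e4 &
    (el$start + el$end) / 2 <= span_hi + 5e4
  expect_equal(nrow(trk), sum(in_win))
  expect_true(all(trk$iscore >= 1))
  # mirrored landscape gives the mirrored identical track
  L <- max(el$end) + 500
  mir <- retro_elements(el$chrom, L - el$end, L - el$start,
                        ifelse(el$strand == "+", "-", "+"), el$family,
                        el$subfamily)
  gm <- gene_model(g$gene_id, g$chrom, L - rev(g$exons$end),
                   L - rev(g$exons$start), flank_bp = g$flank_bp,
                   context_bp = g$context_bp)
  trk_m <- landscape_track(gm, mir, s, window_bp = 5e4, apsn_max = 10)
  expect_equal(trk_m$iscore, rev(trk$iscore), tolerance = 1e-12)
  expect_equal(trk_m$midpoint, rev(L - trk$midpoint))
})

test_that("report writers emit the gene, exon, track and matrix tables", {
  set.seed(47)
  el <- random_landscape(30)
  g <- random_gene(2, min(el$start), max(el$end))
  g$gene_id <- "G1"
  rep_ <- score_genes(list(g), el, fake_surface(0.8), dm, apsn_max = 10)
  dir <- withr::local_tempdir()
  write_stability_report(rep_, dir)
  genes_tab <- read.table(file.path(dir, "gene_stability.tsv"),
                          header = TRUE, sep = "\t")
  expect_equal(genes_tab$gene_id, "G1")
  expect_true(all(c("n_exons", "n_alu", "alu_density_per_mb",
                    "stability") %in% names(genes_tab)))
  exons_tab <- read.table(file.path(dir, "exon_stability.tsv"),
                          header = TRUE, sep = "\t")
  expect_equal(nrow(exons_tab), 2L)
  trk <- landscape_track(g, el, fake_surface(0.8), window_bp = 5e4,
                         apsn_max = 10)
  f <- file.path(dir, "track.bedgraph")
  write_iscore_track(trk, f)
  expect_equal(nrow(read.table(f)), nrow(trk))
})
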