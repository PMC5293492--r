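# Small configurations keep the generator tests fast; scale-sensitive
# recovery properties are exercised at study scale in test-acceptance.R.
small_cfg <- function(...) {
  defaults <- list(seed = 5, n_mirnas = 6, n_genes = 60, utr_length = 300,
                   planted_cotarget_fraction = 0.1, n_nonbrain_cotargets = 2,
                   n_pathways = 4, pathway_size = 8, enriched_overlap = 3,
                   focal_pathway_targets = 3, n_extra_focal_genes = 1,
                   n_background_features = 20)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("fixed seed gives bit-identical generator output; seeds differ", {
  cfg <- small_cfg()
  m1 <- simulate_mirnas(cfg)
  m2 <- simulate_mirnas(cfg)
  expect_identical(m1, m2)
  t1 <- simulate_transcriptome(cfg, m1)
  t2 <- simulate_transcriptome(cfg, m1)
  expect_identical(t1, t2)
  e1 <- simulate_expression(cfg)
  expect_identical(e1, simulate_expression(cfg))
  m3 <- simulate_mirnas(small_cfg(seed = 6))
  expect_false(identical(unname(m1), unname(m3)))
})

test_that("simulated miRNAs have the requested count and distinct mutable seeds", {
  m <- simulate_mirnas(sim_config(seed = 2, n_mirnas = 21))
  expect_length(m, 21)
  seeds <- vapply(m, seed_of, character(1))
  expect_identical(nchar(seeds), rep(7L, 21), ignore_attr = TRUE)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(grepl("^[ACGU]{22}$", m)))
  expect_false(any(substr(m, 4, 6) == "AAU"))
})

test_that("background UTRs carry no 6mer-or-stronger site for any miRNA", {
  cfg <- small_cfg()
  m <- simulate_mirnas(cfg)
  tr <- simulate_transcriptome(cfg, m)
  background <- setdiff(names(tr$utrs), names(tr$truth$assignments))
  withr::with_seed(1, picked <- sample(background, 15))
  for (g in picked) {
    for (mi in names(m)) {
      expect_identical(nrow(oracle_scan(m[[mi]], tr$utrs[[g]])), 0L)
    }
  }
})

test_that("planted-site coordinates equal the scanner's on the generated UTRs", {
  cfg <- small_cfg()
  m <- simulate_mirnas(cfg)
  tr <- simulate_transcriptome(cfg, m)
  expect_gt(nrow(tr$truth$planted_sites), 0)
  scanned <- scan_sites(m, tr$utrs, min_class = "6mer")
  key <- function(df) sort(paste(df$gene, df$mirna, df$site_class,
                                 df$start, df$end))
  expect_identical(key(scanned), key(tr$truth$planted_sites))
  # and the oracle agrees with the recorded coordinates site by site
  for (i in seq_len(min(10, nrow(tr$truth$planted_sites)))) {
    s <- tr$truth$planted_sites[i, ]
    o <- oracle_scan(m[[s$mirna]], tr$utrs[[s$gene]])
    expect_true(any(o$site_class == s$site_class & o$start == s$start &
                      o$end == s$end))
  }
})

test_that("zero co-target fraction plants nothing", {
  cfg <- small_cfg(planted_cotarget_fraction = 0)
  tr <- simulate_transcriptome(cfg, simulate_mirnas(cfg))
  expect_identical(tr$truth$cotargeted_genes, character(0))
  expect_identical(nrow(tr$truth$planted_sites), 0L)
})

test_that("co-targeting ground truth follows the >=3 distinct-miRNA rule", {
  cfg <- small_cfg()
  m <- simulate_mirnas(cfg)
  asg <- list(GENE0001 = names(m)[1:3], GENE0002 = names(m)[1:2])
  tr <- simulate_transcriptome(cfg, m, assignments = asg)
  expect_identical(tr$truth$cotargeted_genes, "GENE0001")
})

test_that("noiseless expression reproduces the planted group means exactly", {
  ids <- sprintf("mir-%02d", 1:4)
  cfg <- sim_config(seed = 9, n_mirnas = 4, noise_cv = 0,
                    n_background_features = 2,
                    class_assignments = setNames(c("I", "II", "III", "none"),
                                                 ids))
  ex <- simulate_expression(cfg)
  fc <- normalize_and_fold(ex$expression)
  for (f in c(ids, "array-mir-001")) {
    cl <- if (f %in% ids) cfg$class_assignments[[f]] else "none"
    means <- cfg$class_means[[cl]]
    expect_equal(fc$fold[fc$feature == f & fc$group == "trained"],
                 rep(means[["trained"]], 3))
    expect_equal(fc$fold[fc$feature == f & fc$group == "immediate"],
                 rep(means[["immediate"]], 3))
    expect_equal(fc$fold[fc$feature == f & fc$group == "naive"],
                 rep(1, 3), tolerance = 1e-12)
  }
})

test_that("invalid configurations and class labels are rejected", {
  expect_error(sim_config(n_mirnas = 2), "n_mirnas")
  expect_error(sim_config(planted_cotarget_fraction = 1.2))
  expect_error(sim_config(noise_cv = -0.1))
  expect_error(sim_config(class_means = list(
    I = c(immediate = 1, trained = 0.5),
    II = c(immediate = 1.8, trained = 3),
    III = c(immediate = 2, trained = 2),
    none = c(immediate = 1, trained = 1))), "must be >= 1")
  cfg <- small_cfg(class_assignments = setNames(
    c("I", "II", "IV", "none", "none", "none"), sprintf("mir-%02d", 1:6)))
  expect_error(simulate_expression(cfg), "unknown induction class")
})

test_that("a UTR too short for the requested sites fails loudly", {
  cfg <- small_cfg(utr_length = 20)
  m <- simulate_mirnas(cfg)
  asg <- list(GENE0001 = names(m)[1:3])
  expect_error(simulate_transcriptome(cfg, m, assignments = asg), "too short")
})

test_that("study-level geometry plants the focal miRNA as top pathway regulator", {
  cfg <- small_cfg()
  st <- simulate_study(cfg)
  expect_identical(st$truth$focal_mirna, "mir-01")
  expect_true(st$truth$enriched_pathway %in% names(st$pathways))
  pw <- st$pathways[[st$truth$enriched_pathway]]
  expect_length(pw, cfg$pathway_size)
  expect_identical(length(intersect(pw, st$truth$cotargeted_brain)),
                   as.integer(cfg$enriched_overlap))
  # decoy co-targets are excluded from the brain universe
  expect_length(intersect(st$truth$nonbrain_cotargeted, st$universe), 0)
  expect_true(all(st$truth$cotargeted_brain %in% st$universe))
})
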