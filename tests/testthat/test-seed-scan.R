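test_that("seed extraction returns miRNA positions 2-8", {
  expect_identical(seed_of("UAGCAGCAA"), "AGCAGCA")
  withr::with_seed(1, {
    s <- rand_seq(22)
    expect_identical(nchar(seed_of(s)), 7L)
    expect_identical(seed_of(s), seed_of(s))
    expect_identical(seed_of(s), substr(s, 2, 8))
  })
  expect_error(seed_of("UAGCAGC"), "shorter than 8")
})

test_that("the forced 8mer example is found, mutated and abolished", {
  mir <- "UAGCAGCAA"
  utr <- c(g1 = "AAAATGCTGCTAAAAA")
  sites <- find_seed_sites(mir, utr)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$site_class, "8mer")
  expect_identical(sites$start, 4L)
  expect_identical(sites$end, 12L)
  expect_identical(unname(substr(utr, 5, 12)), "TGCTGCTA")

  mut <- mutate_seed_region(mir, utr, sites[1, ])
  expect_identical(unname(mut), "AAAATGATTCTAAAAA")
  rescan <- find_seed_sites(mir, mut, min_class = "6mer")
  expect_false(any(rescan$start < 12 & rescan$end > 4))
  # the site is gone, so mutating again violates the precondition
  expect_error(mutate_seed_region(mir, mut, sites[1, ]), "not found")
})

test_that("no-complementarity and empty UTRs give empty site lists", {
  expect_identical(nrow(find_seed_sites("UAGCAGCAA", "CCCCCCCCCC")), 0L)
  expect_identical(nrow(find_seed_sites("UAGCAGCAA", "")), 0L)
  expect_error(find_seed_sites("UAGCAGCAA", c(bad = "ACGTNNN")), "bad")
})

test_that("scanner matches the exhaustive per-offset oracle on random pairs", {
  withr::with_seed(42, {
    n_checked <- 0L
    for (i in 1:60) {
      mir <- rand_seq(22)
      utr <- rand_seq(300, c("A", "C", "G", "T"))
      # embed extra site material in half the cases so all classes occur
      if (i %% 2 == 0) {
        s7 <- oracle_revcomp(substr(chartr("U", "T", mir), 2, 8))
        ins <- sample(c(paste0(s7, "A"), s7, paste0(substr(s7, 2, 7), "A"),
                        substr(s7, 2, 7)), 1)
        at <- sample(50:200, 1)
        substr(utr, at, at + nchar(ins) - 1) <- ins
      }
      for (mc in c("6mer", "7mer-A1", "8mer")) {
        got <- find_seed_sites(mir, utr, min_class = mc)
        want <- oracle_scan(mir, utr, min_class = mc)
        expect_identical(got[, c("site_class", "start", "end")], want)
        expect_identical(is_target(mir, utr, min_class = mc), nrow(want) > 0)
        n_checked <- n_checked + nrow(want)
      }
    }
    expect_gt(n_checked, 20)  # the comparison actually exercised sites
  })
})

test_that("scanning is U/T symmetric and reports the strongest class", {
  withr::with_seed(7, {
    for (i in 1:20) {
      mir <- rand_seq(22)
      utr <- rand_seq(200, c("A", "C", "G", "T"))
      s7 <- oracle_revcomp(substr(chartr("U", "T", mir), 2, 8))
      substr(utr, 90, 97) <- paste0(s7, "A")  # guaranteed 8mer locus
      utr_u <- chartr("T", "U", utr)
      expect_identical(find_seed_sites(mir, utr, min_class = "6mer"),
                       find_seed_sites(mir, utr_u, min_class = "6mer"))
      sites <- find_seed_sites(mir, utr, min_class = "6mer")
      # planted at 1-based 90..97, i.e. 0-based half-open [89, 97)
      eight <- sites[sites$start == 89L, ]
      expect_identical(eight$site_class, "8mer")
      # the 8mer locus also satisfies the nested weaker patterns
      expect_identical(substr(utr, 90, 96), s7)                       # 7mer-m8
      expect_identical(substr(utr, 91, 97), paste0(substr(s7, 2, 7), "A"))
      # but is reported once, as 8mer only
      expect_identical(sum(sites$start >= 89 & sites$end <= 97), 1L)
    }
  })
})

test_that("a seed whose ATT mutation is an identity fails the abolition contract", {
  # miRNA positions 4-6 = AAU makes the target-side triplet already ATT
  mir <- "GAAAAUGCAAAAAAAAAAAAAA"
  expect_identical(substr(mir, 4, 6), "AAU")
  s7 <- oracle_revcomp(substr(chartr("U", "T", mir), 2, 8))
  utr <- c(g = paste0("CCGCCGCC", s7, "A", "CCGCCGCC"))
  sites <- find_seed_sites(mir, utr)
  expect_identical(sites$site_class[1], "8mer")
  expect_error(mutate_seed_region(mir, utr, sites[1, ]), "failed to abolish")
})

test_that("batch scanning equals per-pair scanning", {
  withr::with_seed(13, {
    mirnas <- setNames(replicate(4, rand_seq(22)), paste0("m", 1:4))
    utrs <- setNames(replicate(6, rand_seq(250, c("A", "C", "G", "T"))),
                     paste0("g", 1:6))
    s7 <- oracle_revcomp(substr(chartr("U", "T", mirnas[["m2"]]), 2, 8))
    substr(utrs[["g3"]], 100, 107) <- paste0(s7, "A")
    got <- scan_sites(mirnas, utrs, min_class = "6mer")
    single <- do.call(rbind, lapply(names(mirnas), function(mi) {
      do.call(rbind, lapply(names(utrs), function(g) {
        find_seed_sites(mirnas[[mi]], utrs[g], min_class = "6mer",
                        mirna_id = mi, gene = g)
      }))
    }))
    key <- function(df) sort(paste(df$gene, df$mirna, df$site_class,
                                   df$start, df$end))
    expect_identical(key(got), key(single))
    expect_error(scan_sites(mirnas, c(utrs, utrs[1])), "duplicate gene")
  })
})
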