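test_that("metabolite db: size, uniqueness, and exact isobar pair structure", {
  db <- generate_metabolite_db(1, c(100, 200), seed = 1)
  expect_identical(nrow(db), 1L)
  expect_length(attr(db, "isobar_groups"), 0)

  db <- generate_metabolite_db(500, c(60, 1000), isobar_fraction = 0.1, seed = 1)
  expect_identical(nrow(db), 500L)
  expect_false(anyDuplicated(db$id) > 0)
  # brute-force pairwise ppm scan: exactly floor(0.1*500) two-membered groups
  pp <- abs(outer(db$mass, db$mass, "-")) /
    matrix(db$mass, 500, 500, byrow = TRUE) * 1e6
  adj <- (pp <= 2) | t(pp <= 2)
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  expect_identical(sum(deg == 1), 100L)  # members of 2-groups
  expect_identical(sum(deg > 1), 0L)     # no larger groups
  expect_length(attr(db, "isobar_groups"), 50)

  expect_error(generate_metabolite_db(5, c(100, 200), isobar_fraction = 0.9),
               "impossible isobar fraction")
  expect_error(generate_metabolite_db(10, c(10, 2000)), "mass_range")
})

test_that("two records with identical masses both annotate the same peak", {
  db <- data.frame(id = c("A", "B"), name = c("Alpha", "Beta"),
                   mass = c(150.05, 150.05))
  means <- matrix(c(5, 6), 1, 2,
                  dimnames = list("150.050000", c("s1", "s2")))
  res <- annotate_peaks(means, db)
  expect_identical(res$report$n_matches, 2L)
  expect_identical(rownames(res$matrix), "Alpha/Beta")
})

test_that("study design invariants are enforced", {
  expect_error(study_design(n_planted_reversing = 40,
                            n_planted_discriminative = 30), "reversing")
  expect_error(study_design(effect_size = -1), "effect_size")
  expect_error(study_design(n_planted_discriminative = 300, n_peaks = 200),
               "exceed")
  expect_error(study_design(covariate_links = data.frame(
    feature = 1, covariate = "LVMi", r = 1.5)), "\\[-1, 1\\]")
})

test_that("simulation is deterministic given the design seed", {
  s1 <- small_study(seed = 9, n_peaks = 60, n_planted = 5, n_reversing = 2)
  s2 <- small_study(seed = 9, n_peaks = 60, n_planted = 5, n_reversing = 2)
  expect_identical(s1$run1_peaks, s2$run1_peaks)
  expect_identical(s1$run2_peaks, s2$run2_peaks)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_study(seed = 10, n_peaks = 60, n_planted = 5, n_reversing = 2)
  expect_false(identical(s1$run1_peaks, s3$run1_peaks))
})

test_that("zero triplicate CV gives identical replicates; structure is correct", {
  st <- small_study(seed = 3, n_peaks = 50, n_planted = 5, n_reversing = 2,
                    triplicate_cv = 0)
  sample_of <- sub("\\.[0-9]+$", "", colnames(st$run1_peaks))
  for (s in unique(sample_of)) {
    block <- st$run1_peaks[, sample_of == s, drop = FALSE]
    expect_identical(ncol(block), 3L)
    expect_equal(block[, 1], block[, 2])
    expect_equal(block[, 1], block[, 3])
  }
  # anchor feasibility: case-pre samples in both runs
  pre <- unique(sub("\\.[0-9]+$", "", grep("_pre", colnames(st$run2_peaks),
                                           value = TRUE)))
  expect_true(all(paste0(pre, ".1") %in% colnames(st$run1_peaks)))
  expect_true(length(pre) >= 2)
})

test_that("planted features carry the designed effect size", {
  # recompute Cohen's d from the generated matrices over several seeds
  ds <- vapply(1:6, function(s) {
    st <- small_study(seed = 100 + s, n_peaks = 120, n_planted = 20,
                      n_reversing = 10, decoy_fraction = 0,
                      isobar_fraction = 0)
    lg <- log10(average_triplicates(st$run1_peaks))
    ip <- match(st$truth$planted_feature_ids, st$metabolite_db$id)
    ctrl <- grep("^C", colnames(lg)); cas <- grep("^AS", colnames(lg))
    mean(abs(rowMeans(lg[ip, cas]) - rowMeans(lg[ip, ctrl])) /
           sqrt((apply(lg[ip, cas], 1, var) + apply(lg[ip, ctrl], 1, var)) / 2))
  }, numeric(1))
  expect_equal(mean(ds), 2, tolerance = 0.2)
})

test_that("every db peak m/z is within 2 ppm of exactly one generating mass; decoys beyond 5", {
  st <- small_study(seed = 5, n_peaks = 100, n_planted = 10, n_reversing = 5)
  mz <- as.numeric(rownames(st$run1_peaks))
  pm <- st$truth$peak_map
  for (k in seq_along(mz)) {
    dppm <- abs(mz[k] - st$metabolite_db$mass) / st$metabolite_db$mass * 1e6
    if (pm$metabolite_id[k] == "decoy") {
      expect_gt(min(dppm), 5)
    } else {
      gen <- match(pm$metabolite_id[k], st$metabolite_db$id)
      expect_lt(dppm[gen], 2)
    }
  }
})

test_that("fixtures round-trip losslessly and are byte-identical for a fixed seed", {
  st <- small_study(seed = 21, n_peaks = 40, n_planted = 4, n_reversing = 2)
  d1 <- withr::local_tempdir()
  paths <- write_fixtures(st, d1)
  back <- read_fixtures(d1)
  expect_equal(back$run1_peaks, st$run1_peaks)
  expect_equal(back$run2_peaks, st$run2_peaks)
  expect_equal(back$metabolite_db$mass, st$metabolite_db$mass)
  expect_identical(back$clinical$sample_id, st$clinical$sample_id)
  expect_identical(sort(back$truth$planted_feature_ids),
                   sort(st$truth$planted_feature_ids))
  expect_length(back$truth$planted_feature_ids, 4L)

  d2 <- withr::local_tempdir()
  st_again <- small_study(seed = 21, n_peaks = 40, n_planted = 4,
                          n_reversing = 2)
  write_fixtures(st_again, d2)
  for (f in basename(paths))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})
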