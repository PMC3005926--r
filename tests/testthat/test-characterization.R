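premirna_stub <- function(chrom, start, end, id = NULL) {
  tibble::tibble(
    premirna_id = id %||% sprintf("p%02d", seq_along(start)),
    chrom = chrom, start = as.integer(start), end = as.integer(end)
  )
}

test_that("cluster chaining obeys the 10 kb window inclusively", {
  # six precursors 1 kb apart form one six-member cluster
  s <- seq(0, by = 1140, length.out = 6)
  six <- premirna_stub("chr21", s, s + 140)
  got <- detect_clusters(six)
  expect_equal(nrow(got), 1L)
  expect_equal(got$n_members, 6L)
  expect_setequal(got$members[[1]], six$premirna_id)
  # 10,000 bp gap clusters; 10,001 does not
  at <- premirna_stub("chr1", c(0, 140 + 10000), c(140, 280 + 10000))
  expect_equal(nrow(detect_clusters(at)), 1L)
  over <- premirna_stub("chr1", c(0, 140 + 10001), c(140, 280 + 10001))
  expect_equal(nrow(detect_clusters(over)), 0L)
})

test_that("cluster chaining equals the all-pairs single-linkage oracle", {
  withr::local_seed(60)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    start <- sort(sample.int(80000, n)) * 1L
    df <- premirna_stub(sample(c("chr1", "chr2"), n, replace = TRUE),
                        start, start + 140L)
    got <- detect_clusters(df)
    want <- oracle_clusters(df, 10000)
    got_sets <- lapply(got$members, sort)
    expect_equal(length(got_sets), length(want))
    for (w in want) {
      expect_true(any(vapply(got_sets, identical, logical(1), y = w)))
    }
    # invariant to input order
    shuf <- detect_clusters(df[sample(n), ])
    expect_equal(dplyr::arrange(got, cluster_id),
                 dplyr::arrange(shuf, cluster_id))
  }
})

test_that("cluster member counts account for all clustered precursors", {
  run <- default_run(7)
  cl <- run$result$clusters
  expect_equal(sum(cl$n_members), length(unique(unlist(cl$members))))
  expect_equal(run$result$summary$n_premirna_clustered, sum(cl$n_members))
})

test_that("arm categories follow the dominance ratio thresholds", {
  expect_equal(arm_category(100L, 0L), "5P_only")
  expect_equal(arm_category(0L, 100L), "3P_only")
  expect_equal(arm_category(300L, 100L), "5P_dominant")
  expect_equal(arm_category(100L, 300L), "3P_dominant")
  expect_equal(arm_category(120L, 100L), "equal")
  expect_equal(arm_category(200L, 100L), "5P_dominant")  # ratio 2 inclusive
  expect_equal(arm_category(199L, 100L), "equal")
})

test_that("arm profiles partition pre-miRNAs and sum their copies", {
  run <- default_run(7)
  p <- run$result$premirnas
  lvls <- c("5P_only", "3P_only", "5P_dominant", "3P_dominant", "equal")
  expect_true(all(p$arm_category %in% lvls))
  freq <- table(p$arm_category) / nrow(p)
  expect_equal(sum(freq), 1)
  tot <- vapply(p$isomirs, function(i)
    sum(i$copy_number[i$arm != "loop"]), integer(1))
  expect_equal(p$copies_5p + p$copies_3p, tot)
})

test_that("cross-species arm-difference classes match their definitions", {
  # candidate both arms, ortholog single-arm -> class 1
  expect_equal(arm_difference_class("5P_dominant", "major", "absent"),
               "class1")
  expect_equal(arm_difference_class("equal", "absent", "major"), "class1")
  # candidate single-arm, ortholog both arms -> class 2
  expect_equal(arm_difference_class("3P_only", "major", "minor"), "class2")
  expect_equal(arm_difference_class("5P_only", "minor", "major"), "class2")
  # candidate and ortholog on exactly opposite arms -> class 3
  expect_equal(arm_difference_class("5P_only", "absent", "major"), "class3")
  expect_equal(arm_difference_class("3P_only", "major", "absent"), "class3")
  # concordant otherwise
  expect_equal(arm_difference_class("5P_only", "major", "absent"),
               "concordant")
  expect_equal(arm_difference_class("equal", "major", "minor"), "concordant")
  expect_true(is.na(arm_difference_class("undetermined", "major", "minor")))
})

test_that("arm-difference classification is symmetric under 5p/3p swap", {
  cats <- c("5P_only", "3P_only", "5P_dominant", "3P_dominant", "equal")
  swap_cat <- c("5P_only" = "3P_only", "3P_only" = "5P_only",
                "5P_dominant" = "3P_dominant", "3P_dominant" = "5P_dominant",
                "equal" = "equal")
  statuses <- c("major", "minor", "absent")
  for (cc in cats) {
    for (o5 in statuses) {
      for (o3 in statuses) {
        if (o5 == "absent" && o3 == "absent") next
        expect_equal(arm_difference_class(cc, o5, o3),
                     arm_difference_class(swap_cat[[cc]], o3, o5),
                     info = paste(cc, o5, o3))
      }
    }
  }
})

test_that("quartile split is contiguous with remainder to earlier quarters", {
  fam <- tibble::tibble(
    family = sprintf("mir-%02d", 1:10),
    conservation_level = 1:10,
    expression_level = rep(100L, 10)
  )
  ce <- conservation_expression(fam)
  expect_equal(ce$quartiles$n, c(3L, 3L, 2L, 2L))
  expect_equal(ce$data$quartile,
               rep(c("Q1", "Q2", "Q3", "Q4"), c(3, 3, 2, 2)))
  expect_error(conservation_expression(fam[1:5, ]), "at least")
})

test_that("quartile t-tests behave under the null and detect a gradient", {
  null_p <- numeric(0)
  sig_all <- logical(0)
  for (s in 1:40) {
    fam0 <- simulate_family_records(n_families = 100, gradient = 0,
                                    sigma = 0.5, seed = s)
    null_p <- c(null_p, conservation_expression(fam0)$tests$p_value)
    fam2 <- simulate_family_records(n_families = 100, gradient = 2,
                                    sigma = 0.5, seed = s)
    ce2 <- conservation_expression(fam2)
    sig_all <- c(sig_all, all(ce2$tests$p_value < 0.05))
    if (s == 1) {
      expect_false(is.unsorted(ce2$quartiles$median))
      expect_true(glance(ce2)$monotone_medians)
    }
  }
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.05)
  expect_true(all(sig_all))
})

test_that("result objects expose tidy/glance/autoplot interfaces", {
  fam <- simulate_family_records(n_families = 40, gradient = 1, seed = 2)
  ce <- conservation_expression(fam)
  expect_s3_class(tidy(ce), "tbl_df")
  expect_named(glance(ce), c("n_families", "n_groups", "min_p_value",
                             "monotone_medians"))
  expect_s3_class(autoplot(ce), "ggplot")
  run <- default_run(7)
  expect_s3_class(glance(run$result), "tbl_df")
  expect_s3_class(plot_arm_categories(run$result$premirnas), "ggplot")
  expect_s3_class(plot_isomir_stack(run$result$premirnas,
                                    run$result$premirnas$premirna_id[1]),
                  "ggplot")
  expect_s3_class(glance(run$result$model), "tbl_df")
})
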