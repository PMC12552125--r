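test_that("blank thresholds follow the 2x rule", {
  mat <- rbind("CE 18:1" = c(10, 10, 2, 4),
               "PC 34:2" = c(10, 10, NA, NA),
               "TG 52:3" = c(10, 10, 1, 5))
  colnames(mat) <- c("s1", "s2", "b1", "b2")
  ds <- make_fixture_dataset(mat, c("sample", "sample", "blank", "blank"))
  thr <- blank_threshold(ds)
  expect_equal(unname(thr["CE 18:1"]), 6)    # 2 x mean(2, 4)
  expect_equal(unname(thr["PC 34:2"]), 0)    # all-missing blanks -> 0
  thr_max <- blank_threshold(ds, filter_params(blank_statistic = "max"))
  expect_equal(unname(thr_max["CE 18:1"]), 8)

  no_blank <- make_fixture_dataset(mat[, 1:2], c("sample", "sample"))
  expect_error(blank_threshold(no_blank), class = "no_blank_error")
})

test_that("verdicts follow the 80%/60% rule with reintroduction", {
  ds <- tiny_dataset()
  res <- apply_blank_filter(ds)
  v <- setNames(res$report$verdict, res$report$species)
  expect_equal(unname(v["CE 18:1"]), "retained")
  expect_equal(unname(v["SM 34:1"]), "retained")     # 5/6 ~ 0.83 >= 0.8
  expect_equal(unname(v["TG 52:3"]), "reintroduced") # 2/6 global, 2/2 in B
  expect_equal(unname(v["PC 34:2"]), "removed")
  expect_equal(unname(v["FFA 18:1"]), "retained")    # threshold 0
  expect_equal(res$report$best_group[res$report$species == "TG 52:3"], "B")
  # filtered dataset = retained + reintroduced, missing values untouched
  expect_setequal(rownames(res$dataset$concentrations),
                  names(v)[v != "removed"])
  expect_true(is.na(res$dataset$concentrations["SM 34:1", "s3"]))
})

test_that("boundary fractions exactly at 0.8 and 0.6 pass", {
  # 5 biological samples: 4/5 = 0.8 exactly
  mat <- rbind("CE 18:1" = c(10, 10, 10, 10, 1, 2, 2),
               "TG 52:3" = c(10, 10, 10, 1, 1, 2, 2))
  colnames(mat) <- c(paste0("s", 1:5), "b1", "b2")
  ds <- make_fixture_dataset(mat, c(rep("sample", 5), "blank", "blank"),
                             group = c("A", "A", "A", "B", "B", NA, NA))
  res <- apply_blank_filter(ds)
  v <- setNames(res$report$verdict, res$report$species)
  expect_equal(unname(v["CE 18:1"]), "retained")       # exactly 0.8
  # TG: 3/5 = 0.6 global < 0.8; group A 3/3 = 1 -> reintroduced
  expect_equal(unname(v["TG 52:3"]), "reintroduced")

  # exactly at the 0.6 group boundary
  mat2 <- rbind("CE 18:1" = c(10, 10, 10, 1, 1, 1, 1, 1, 1, 1, 2, 2))
  colnames(mat2) <- c(paste0("s", 1:10), "b1", "b2")
  ds2 <- make_fixture_dataset(mat2, c(rep("sample", 10), "blank", "blank"),
                              group = c(rep("A", 5), rep("B", 5), NA, NA))
  res2 <- apply_blank_filter(ds2)
  expect_equal(res2$report$verdict, "reintroduced")    # 3/5 = 0.6 in A
})

test_that("verdicts match the brute-force oracle on 100 random datasets", {
  for (seed in 1:100) {
    r <- random_small_dataset(seed)
    ds <- fixture_dataset_from_random(r)
    res <- apply_blank_filter(ds)
    oracle <- brute_force_filter(ds$concentrations,
                                 ds$samples$sample_type, ds$samples$group)
    got <- setNames(res$report$verdict, res$report$species)
    expect_identical(got[names(oracle)], oracle,
                     label = sprintf("seed %d", seed))
  }
})

test_that("filter is idempotent and monotone in its parameters", {
  for (seed in c(3, 17, 58)) {
    ds <- fixture_dataset_from_random(random_small_dataset(seed))
    res <- apply_blank_filter(ds)
    again <- apply_blank_filter(res$dataset)
    expect_equal(nrow(again$dataset$concentrations),
                 nrow(res$dataset$concentrations))
    expect_true(all(again$report$verdict != "removed"))

    kept <- function(params) {
      rep <- apply_blank_filter(ds, params)$report
      rep$species[rep$verdict != "removed"]
    }
    base <- kept(filter_params())
    expect_true(all(base %in% kept(filter_params(blank_fold = 1.5))))
    expect_true(all(base %in% kept(filter_params(global_fraction = 0.6))))
  }
})

test_that("empty designs and report export behave", {
  mat <- matrix(c(1, 2), 1, 2, dimnames = list("CE 18:1", c("b1", "b2")))
  ds <- make_fixture_dataset(mat, c("blank", "blank"))
  expect_error(apply_blank_filter(ds), class = "empty_design_error")

  res <- apply_blank_filter(tiny_dataset())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_filter_report(res$report, csv, js)
  expect_equal(nrow(read.csv(csv)), 5L)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$totals$removed, 1L)
  expect_equal(summ$params$blank_fold, 2)
})
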