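test_that("long Cq tables with technical duplicates round-trip field for field", {
  set.seed(11)
  n <- 16L; G <- 11L
  rep_cq <- array(stats::runif(n * G * 2, 18, 32), c(n, G, 2),
                  dimnames = list(sprintf("S%02d", 1:n), sprintf("sno%d", 1:G), NULL))
  cq <- apply(rep_cq, c(1, 2), mean)
  groups <- rep(c("non-treated", "sham", "SNI"), c(5, 6, 5))
  ds <- cq_dataset(cq, groups, tissue = "DRG", setting = "common_threshold",
                   replicate_cq = rep_cq)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(ds, path)
  back <- read_cq_table(path)
  expect_equal(back$cq, ds$cq)
  expect_equal(back$replicate_cq, ds$replicate_cq)
  expect_identical(back$groups, ds$groups)
  expect_identical(back$tissue, "DRG")
  expect_identical(back$setting, "common_threshold")
  expect_identical(dim(back$cq), c(16L, 11L))
  expect_identical(dim(back$replicate_cq), c(16L, 11L, 2L))
})

test_that("row order of the input does not affect the parsed dataset", {
  set.seed(12)
  ds <- make_ds(random_cq(5, 4), tissue = "dhSC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(ds, path)
  lines <- readLines(path)
  shuffled <- c(lines[1L], sample(lines[-1L]))
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuffled, path2)
  a <- read_cq_table(path)
  b <- read_cq_table(path2)
  # sample/gene discovery order differs; content must agree
  expect_equal(b$cq[rownames(a$cq), colnames(a$cq)], a$cq)
  expect_identical(sort(names(b$groups)), sort(names(a$groups)))
  expect_identical(b$groups[names(a$groups)], a$groups)
})

test_that("a single-cell table parses to a 1x1 dataset and wide layout works", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,cq", "m1,ctrl,sno202,25.0"), path)
  ds <- read_cq_table(path)
  expect_equal(unname(ds$cq[1, 1]), 25.0)
  expect_identical(dim(ds$cq), c(1L, 1L))

  wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup\tsno202\tU6",
               "m1\tctrl\t25.0\t21.5",
               "m2\ttreat\t26.0\t21.0"), wide)
  dw <- read_cq_table(wide, format = "wide")
  expect_equal(unname(dw$cq["m2", "U6"]), 21.0)
  expect_identical(colnames(dw$cq), c("sno202", "U6"))
})

test_that("schema, range and consistency errors are reported with context", {
  bad_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,condition,gene,cq", "m1,ctrl,g1,25"), bad_col)
  expect_error(read_cq_table(bad_col), "required column 'group'")

  non_num <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,cq", "m1,ctrl,g1,25", "m2,ctrl,g1,oops"), non_num)
  expect_error(read_cq_table(non_num), "non-numeric cq.*row 2")

  oob <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,cq", "m1,ctrl,g1,25", "m1,ctrl,g2,47.2"), oob)
  expect_error(read_cq_table(oob), "out of range.*row 2")

  confl <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,cq", "m1,ctrl,g1,25", "m1,treat,g2,26"), confl)
  expect_error(read_cq_table(confl), "conflicting group labels: m1")
})

test_that("undetermined wells become missing values, not the cycle count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,cq",
               "m1,ctrl,g1,25.0", "m1,ctrl,g2,Undetermined",
               "m2,ctrl,g1,24.5", "m2,ctrl,g2,31.0"), path)
  ds <- read_cq_table(path)
  expect_true(is.na(ds$cq["m1", "g2"]))
  expect_false(any(ds$cq == 40, na.rm = TRUE))
})

test_that("validate_cq_dataset reports each violation with its location", {
  ds <- make_ds(random_cq(4, 3))
  expect_identical(nrow(validate_cq_dataset(ds)), 0L)

  ds$cq[2, 3] <- -1
  rep <- validate_cq_dataset(ds)
  expect_identical(rep$check, "cq_range")
  expect_match(rep$location, "S02, g3")

  dup <- make_ds(random_cq(4, 3))
  colnames(dup$cq)[2] <- "g1"
  rep2 <- validate_cq_dataset(dup)
  expect_true("unique_genes" %in% rep2$check)

  reps <- array(c(24, 26), dim = c(1, 1, 2), dimnames = list("S1", "g1", NULL))
  bad_mean <- cq_dataset(matrix(30, 1, 1, dimnames = list("S1", "g1")),
                         c(S1 = "A"), replicate_cq = reps)
  expect_true("replicate_mean" %in% validate_cq_dataset(bad_mean)$check)
})

test_that("amplification tables round-trip and reject malformed cycle data", {
  set.seed(13)
  curves <- lapply(1:3, function(i) {
    amplification_curve(paste0("w", i), "g1", paste0("s", i),
                        0.05 + 0.001 * 1.9^(1:12) + stats::rnorm(12, 0, 1e-4))
  })
  names(curves) <- paste0("w", 1:3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_amplification_table(curves, path)
  back <- read_amplification_table(path)
  expect_identical(length(back), 3L)
  expect_equal(back$w2$fluorescence, curves$w2$fluorescence)
  expect_identical(back$w1$cycles, 12L)

  # shuffled rows parse to identical curves
  lines <- readLines(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1L], sample(lines[-1L])), path2)
  back2 <- read_amplification_table(path2)
  expect_equal(back2[names(back)], back)

  # duplicated (well, cycle)
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines, lines[2L]), path3)
  expect_error(read_amplification_table(path3), "duplicated \\(well, cycle\\)")

  # gap in the cycle index
  keep <- !grepl("^w1,g1,s1,5,", lines)
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[keep], path4)
  expect_error(read_amplification_table(path4), "non-contiguous")
})

test_that("a plate of simulated wells parses one curve per well", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_amplification_curves(cfg, wells_per_gene = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_amplification_table(sim$curves, path)
  back <- read_amplification_table(path)
  expect_identical(length(back), 22L)
  expect_true(all(vapply(back, function(cu) cu$cycles, integer(1)) == 40L))
})
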