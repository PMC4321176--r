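test_that("beta_matrix validates values, ids and detection shape", {
  m <- matrix(c(0.1, 0.9, 0.5, 0.4, 0.2, 0.7), 3, 2,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  bm <- beta_matrix(m)
  expect_identical(bm$beta, m)
  expect_identical(probe_ids(bm), c("cg1", "cg2", "cg3"))

  bad <- m; bad["cg2", "s2"] <- 1.2
  expect_error(beta_matrix(bad), "cg2.*s2|s2.*cg2")

  dup <- m; rownames(dup) <- c("cg1", "cg1", "cg3")
  expect_error(beta_matrix(dup), "duplicate probe ids")

  expect_error(beta_matrix(m, matrix(0.01, 2, 2)), "shape")
})

test_that("beta matrix write/read round-trips a cohort-sized matrix", {
  set.seed(42)
  m <- matrix(runif(998 * 25), 998, 25,
              dimnames = list(sprintf("cg%04d", 1:998),
                              sprintf("s%02d", 1:25)))
  dp <- matrix(runif(998 * 25, 0, 0.05), 998, 25, dimnames = dimnames(m))
  bm <- beta_matrix(m, dp)
  bfile <- withr::local_tempfile(fileext = ".tsv")
  dfile <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(bm, bfile, dfile)
  back <- read_beta_matrix(bfile, dfile)
  expect_identical(dimnames(back$beta), dimnames(m))
  expect_lt(max(abs(back$beta - m)), 1e-9)
  expect_lt(max(abs(back$detection_p - dp)), 1e-9)

  # determinism: writing the same matrix twice is byte-identical
  bfile2 <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(bm, bfile2)
  expect_identical(readBin(bfile, "raw", file.size(bfile)),
                   readBin(bfile2, "raw", file.size(bfile2)))
})

test_that("read_beta_matrix rejects out-of-range and non-numeric cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "cg1\t0.5\t1.2", "cg2\t0.1\t0.2"), f)
  expect_error(read_beta_matrix(f), "cg1.*s2|s2.*cg1")
  writeLines(c("probe_id\ts1\ts2", "cg1\t0.5\toops", "cg2\t0.1\t0.2"), f)
  expect_error(read_beta_matrix(f), "non-numeric")
})

test_that("derive_cpg_class matches an exhaustive truth-table oracle", {
  expect_identical(derive_cpg_class(0.60, 0.80, 600), "HC")
  expect_identical(derive_cpg_class(0.52, 0.50, 300), "IC")
  expect_identical(derive_cpg_class(0.40, 0.20, 100), "LC")
  # strict boundaries fall through to the weaker class
  expect_identical(derive_cpg_class(0.55, 0.80, 600), "IC")
  expect_identical(derive_cpg_class(0.50, 0.48, 200), "LC")
  expect_identical(derive_cpg_class(0.60, NA, 600), "uncategorized")
  expect_error(derive_cpg_class(-0.1, 0.5, 100), "nonnegative")

  oracle <- function(gc, oe, len) {
    if (gc > 0.55 && oe > 0.75 && len > 500) return("HC")
    if (gc > 0.50 && oe > 0.48 && len > 200) return("IC")
    "LC"
  }
  grid <- expand.grid(gc = c(0.40, 0.50, 0.505, 0.55, 0.555, 0.60),
                      oe = c(0.30, 0.48, 0.485, 0.75, 0.755, 0.90),
                      len = c(100, 200, 201, 500, 501, 600))
  got <- derive_cpg_class(grid$gc, grid$oe, grid$len)
  want <- mapply(oracle, grid$gc, grid$oe, grid$len)
  expect_identical(got, unname(want))
})

test_that("align_matched reorders probes, intersects subjects, idempotent", {
  set.seed(7)
  n <- 25
  a <- rand_beta(12, n, "a")
  b_vals <- a$beta + matrix(rnorm(12 * n, 0, 0.01), 12, n)
  b_vals <- pmin(pmax(b_vals, 0), 1)
  scramble <- sample(12)
  b <- beta_matrix(`dimnames<-`(b_vals[scramble, ],
                                list(rownames(a$beta)[scramble],
                                     paste0("b", 1:n))))
  subj <- sprintf("S%02d", 1:n)
  sheet <- data.frame(sample_id = c(colnames(a$beta), colnames(b$beta)),
                      subject_id = rep(subj, 2),
                      tissue = rep(c("A", "B"), each = n),
                      stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = rownames(a$beta), stringsAsFactors = FALSE)

  ds <- align_matched(a, b, sheet, ann)
  expect_identical(rownames(ds$tissue_a$beta), rownames(ds$tissue_b$beta))
  expect_identical(ds$subject_order, subj)
  # values line up by subject despite the scrambled input order
  expect_equal(ds$tissue_b$beta["cg005", 3],
               b$beta["cg005", "b3"])

  # a subject missing from tissue B is dropped with a warning
  b24 <- subset_beta_matrix(b, samples = paste0("b", 1:(n - 1)))
  expect_warning(ds24 <- align_matched(a, b24, sheet, ann), "S25")
  expect_identical(n_subjects(ds24), 24L)

  # idempotence: aligning an aligned dataset changes nothing
  ds2 <- align_matched(ds$tissue_a, ds$tissue_b, ds$samples, ds$annotation)
  expect_identical(ds2$tissue_a$beta, ds$tissue_a$beta)
  expect_identical(ds2$tissue_b$beta, ds$tissue_b$beta)
  expect_identical(ds2$subject_order, ds$subject_order)

  expect_error(align_matched(a, rand_beta(5, 3, "x"), sheet, ann),
               "no overlapping probes|no subjects")
})

test_that("write_results is deterministic and round-trips tables", {
  tab <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    p = c(0.5, 1e-12, 0.25),
                    label = c("x", NA, "z"),
                    flag = c(TRUE, FALSE, NA),
                    stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(tab, f1)
  write_results(tab, f2)
  expect_identical(length(readLines(f1)), 4L)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_results(f1)
  expect_identical(back$probe_id, tab$probe_id)
  expect_equal(back$p, tab$p)
  expect_identical(is.na(back$label), is.na(tab$label))
  expect_error(write_results(data.frame(), f1), "nonempty")
})
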