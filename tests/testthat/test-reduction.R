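mk_table <- function(X) {
  df <- as.data.frame(X)
  df$patient_id <- sprintf("p%02d", seq_len(nrow(df)))
  df$cohort <- "A"
  df$trg <- 0L
  df$label <- 0L
  df
}

test_that("IQR scaling centres the median and flags constant features", {
  tab <- mk_table(data.frame(f1 = c(1, 2, 3, 4, 5), f2 = rep(7, 5)))
  sc <- fit_scaler(tab)
  Xs <- apply_scaler(sc, tab)
  expect_equal(unname(Xs[, "f1"]), c(-1, -0.5, 0, 0.5, 1))
  expect_equal(unname(Xs[, "f2"]), rep(0, 5))
  expect_true(sc$zero_iqr[["f2"]])
  expect_false(sc$zero_iqr[["f1"]])
  # median of every scaled training column is 0 by construction
  set.seed(3)
  tab2 <- mk_table(as.data.frame(matrix(rnorm(200), 20)))
  Xs2 <- apply_scaler(fit_scaler(tab2), tab2)
  expect_lt(max(abs(apply(Xs2, 2, median))), 1e-12)
  expect_error(apply_scaler(sc, tab[, c("patient_id", "f1")]), "missing")
})

test_that("correlation clustering groups duplicates and anti-correlates", {
  set.seed(5)
  base <- rnorm(30)
  tab <- mk_table(data.frame(a = base, b = base, c = -base + rnorm(30, sd = 1e-6),
                             d = rnorm(30)))
  Xs <- apply_scaler(fit_scaler(tab), tab)
  cl <- cluster_features(Xs, threshold = 0.95)
  grp <- function(f) which(vapply(cl$clusters, function(m) f %in% m, logical(1)))
  expect_equal(grp("a"), grp("b"))
  expect_equal(grp("a"), grp("c")) # |r| treats anti-correlation as redundancy
  expect_false(grp("d") == grp("a"))
})

test_that("independent features stay in singleton clusters", {
  set.seed(11)
  X <- matrix(rnorm(200 * 50), 200)
  colnames(X) <- sprintf("f%02d", 1:50)
  tab <- mk_table(as.data.frame(X))
  cl <- cluster_features(apply_scaler(fit_scaler(tab), tab))
  sizes <- lengths(cl$clusters)
  expect_gte(sum(sizes == 1), 45)
})

test_that("meta-features conserve maximum cluster variance and filter by variance", {
  set.seed(13)
  base <- rnorm(40, sd = 2)
  # a symmetric two-point column scales to variance ~0.25 < 0.3 under the
  # IQR scaler, so the variance filter must remove it
  tab <- mk_table(data.frame(a = base, b = base,
                             tiny = rep(c(0, 1), 20),
                             solo = rnorm(40, sd = 2)))
  sc <- fit_scaler(tab)
  Xs <- apply_scaler(sc, tab)
  cl <- cluster_features(Xs)
  pr <- fit_metafeatures(Xs, cl, variance_threshold = 0.3)
  mf <- apply_metafeatures(pr, Xs)
  # duplicate pair collapses to one meta-feature explaining all its variance
  ab_name <- grep("_(a|b)$", pr$names, value = TRUE)
  expect_length(ab_name, 1)
  expect_gte(stats::var(mf[, ab_name]), stats::var(Xs[, "a"]))
  # singleton passthrough is exact
  expect_true("solo" %in% pr$names)
  expect_equal(mf[, "solo"], Xs[, "solo"])
  # the scaled low-variance feature dies at the variance filter
  expect_false(any(grepl("tiny", pr$names)))
})

test_that("the variance threshold is a strict lower bound", {
  set.seed(17)
  n <- 400
  mk_col <- function(target_var) {
    x <- rnorm(n)
    x <- (x - mean(x)) / sd(x) * sqrt(target_var)
    x
  }
  Xs <- cbind(keep = mk_col(0.31), drop = mk_col(0.29))
  cl <- cluster_features(Xs)
  pr <- fit_metafeatures(Xs, cl, variance_threshold = 0.3)
  expect_true("keep" %in% pr$names)
  expect_false("drop" %in% pr$names)
})

test_that("PC signs are fixed and projection is deterministic", {
  set.seed(19)
  base <- rnorm(30)
  tab <- mk_table(data.frame(a = base + rnorm(30, sd = 0.01),
                             b = base + rnorm(30, sd = 0.01)))
  red1 <- fit_reducer(tab, variance_threshold = 0)
  red2 <- fit_reducer(tab, variance_threshold = 0)
  expect_identical(apply_reducer(red1, tab), apply_reducer(red2, tab))
  cp <- red1$projector$components[[1]]
  expect_gt(cp$loading[which.max(abs(cp$loading))], 0)
  expect_equal(sum(cp$loading^2), 1, tolerance = 1e-12)
})

test_that("validation rows never alter the fitted reduction (no leakage)", {
  set.seed(23)
  train <- mk_table(as.data.frame(matrix(rnorm(30 * 8), 30,
                                         dimnames = list(NULL, paste0("f", 1:8)))))
  valid <- as.data.frame(matrix(rnorm(10 * 8, mean = 3), 10,
                                dimnames = list(NULL, paste0("f", 1:8))))
  red <- fit_reducer(train, variance_threshold = 0)
  before <- jsonlite::serializeJSON(larcradiomics:::reducer_to_list(red))
  mf_valid <- apply_reducer(red, valid)
  after <- jsonlite::serializeJSON(larcradiomics:::reducer_to_list(red))
  expect_identical(before, after)
  # refitting with validation rows appended changes the fit; applying the
  # frozen reducer does not
  red_aug <- fit_reducer(rbind(train, mk_table(valid)[names(train)]),
                         variance_threshold = 0)
  expect_false(identical(red_aug$scaler$median, red$scaler$median))
  expect_identical(apply_reducer(red, valid), mf_valid)
})

test_that("reducers serialise to JSON and back without changing projections", {
  set.seed(29)
  tab <- mk_table(as.data.frame(matrix(rnorm(25 * 6), 25,
                                       dimnames = list(NULL, paste0("f", 1:6)))))
  red <- fit_reducer(tab, variance_threshold = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_reducer(red, path)
  red2 <- read_reducer(path)
  expect_equal(apply_reducer(red2, tab), apply_reducer(red, tab),
               tolerance = 1e-12)
})

test_that("non-finite inputs are rejected at application time", {
  set.seed(31)
  tab <- mk_table(as.data.frame(matrix(rnorm(20 * 3), 20,
                                       dimnames = list(NULL, paste0("f", 1:3)))))
  red <- fit_reducer(tab, variance_threshold = 0)
  bad <- tab
  bad$f1[1] <- NA
  expect_error(apply_reducer(red, bad), "non-finite")
})
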