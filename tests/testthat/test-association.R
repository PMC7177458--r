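test_that("intercept-only logit recovers the closed-form MLE", {
  d <- data.frame(y = c(rep(1, 7), rep(0, 3)))
  m <- fit_blr(d, character(0), "y")
  expect_equal(m$coefficients$B[1], log(7 / 3), tolerance = 1e-8)
  expect_equal(unique(round(stats::fitted(m$fit), 10)), 0.7)
  expect_equal(m$accuracy, 0.7)  # all classified active at p = 0.5
})

test_that("binary-predictor OR equals the contingency cross-product ratio", {
  set.seed(23)
  for (i in 1:5) {
    x <- rbinom(400, 1, 0.5)
    y <- rbinom(400, 1, plogis(-0.5 + 1.2 * x))
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    if (any(tab == 0)) next
    or_tab <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
    m <- fit_blr(data.frame(x = x, y = y), "x", "y")
    expect_equal(m$coefficients$OR[m$coefficients$term == "x"], or_tab,
                 tolerance = 1e-6)
  }
})

test_that("fitted probabilities average to the event rate", {
  set.seed(29)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
  d$y <- rbinom(300, 1, plogis(0.3 + 0.8 * d$x1 - 0.5 * d$x2))
  m <- fit_blr(d, c("x1", "x2"), "y")
  expect_equal(mean(stats::fitted(m$fit)), mean(d$y), tolerance = 1e-8)
  ## Wald CI convention
  cf <- m$coefficients
  expect_equal(cf$ci_lo, exp(cf$B - 1.96 * cf$SE))
  expect_equal(cf$ci_hi, exp(cf$B + 1.96 * cf$SE))
  expect_true(all(cf$ci_lo < cf$OR & cf$OR < cf$ci_hi))
})

test_that("degenerate fits error cleanly", {
  d <- data.frame(x = c(0, 0, 0, 1, 1, 1), y = c(0, 0, 0, 1, 1, 1))
  expect_error(fit_blr(d, "x", "y"), "separation")
  expect_error(fit_blr(data.frame(x = 1:5, y = rep(1, 5)), "x", "y"),
               "single class")
  expect_error(fit_blr(data.frame(x = rep(2, 6), y = rep(0:1, 3)), "x", "y"),
               "constant predictor")
})

test_that("confounding check arithmetic and flagging", {
  set.seed(31)
  d <- data.frame(x = rnorm(500))
  d$y <- rbinom(500, 1, plogis(0.2 + 0.6 * d$x))
  m <- fit_blr(d, "x", "y")
  expect_equal(confounding_check(m, m)$change_pct, 0)
  ## direct arithmetic at the 10% boundary
  fake <- function(or) {
    f <- m
    f$coefficients <- data.frame(term = "x", B = log(or), SE = 0.1, p = 0.01,
                                 OR = or, ci_lo = or * 0.8, ci_hi = or * 1.2)
    f
  }
  cc <- confounding_check(fake(1.00), fake(1.10))
  expect_equal(cc$change_pct, 10, tolerance = 1e-9)
  expect_true(cc$flagged)
  expect_false(confounding_check(fake(1.00), fake(1.05))$flagged)
  expect_error(confounding_check(fake(1), fit_blr(d, character(0), "y")),
               "no shared")
})

test_that("a constructed confounder moves the OR by more than 10%", {
  set.seed(37)
  n <- 4000
  z <- rbinom(n, 1, 0.5)                 # confounder: in and out of the model
  x <- rnorm(n, mean = 1.5 * z)          # correlated with z
  y <- rbinom(n, 1, plogis(-1 + 0.3 * x + 1.5 * z))
  d <- data.frame(x = x, y = y, z = z)
  crude <- fit_blr(d, "x", "y")
  adj <- fit_blr(d, c("x", "z"), "y")
  expect_true(confounding_check(crude, adj)$flagged[1])
})

test_that("collinearity diagnostics match the normal-equations oracle", {
  set.seed(41)
  n <- 300
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X[, "c"] <- 0.7 * X[, "a"] + 0.5 * X[, "b"] + 0.4 * rnorm(n)
  d <- as.data.frame(X)
  d$y <- rbinom(n, 1, 0.5)
  rep <- collinearity_diagnostics(d, c("a", "b", "c"), outcome = "y")
  for (j in 1:3) {
    expect_equal(unname(rep$vif[j]), oracle_vif(X, j), tolerance = 1e-8)
  }
  expect_equal(rep$cor_matrix, stats::cor(X), tolerance = 1e-12)
  expect_true(all(rep$vif >= 1))
  expect_true(all(rep$condition_index >= 1 - 1e-9))
  ## cross-check against car's VIF on a linear model
  if (requireNamespace("car", quietly = TRUE)) {
    d$lin <- rnorm(n)
    vc <- car::vif(stats::lm(lin ~ a + b + c, data = d))
    expect_equal(unname(rep$vif), unname(vc), tolerance = 1e-8)
  }
})

test_that("orthogonal predictors give VIF 1; duplicates error", {
  X <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  d <- rbind(X, X)
  d$y <- rep(0:1, each = 8)
  rep <- collinearity_diagnostics(d, c("a", "b", "c"))
  expect_equal(unname(rep$vif), rep(1, 3), tolerance = 1e-12)
  d$dup <- d$a
  expect_error(collinearity_diagnostics(d, c("a", "dup")), "perfect")
  expect_error(collinearity_diagnostics(d, "a"), ">= 2")
})

test_that("model sequence drops a null, collinear predictor and refits", {
  ## records where resident density has no outcome effect and its median
  ## dummy tracks the intersection dummy (schools' ranks agree except the
  ## two straddling the median), so it is non-significant and VIF-flagged
  gen <- function(seed) {
    set.seed(seed)
    n <- 1500
    school <- sample(1:12, n, TRUE)
    ## res ranking = int ranking with the bottom school promoted to the top,
    ## so the two median dummies disagree on exactly two schools wherever
    ## the participant-level cut lands: collinear but never perfectly so
    int_rank <- 1:12
    res_rank <- c(12L, 1:11)
    intd <- (2 + 0.5 * int_rank)[school]
    resd <- (20 + 15 * res_rank)[school]
    mixz <- rnorm(12)[school]
    dist <- rlnorm(n, log(1), 0.5)
    pr <- 1 + rlnorm(n, log(0.25), 0.5)
    ag <- sample(c("child", "adolescent"), n, TRUE)
    eta <- -1.5 + 0.5 * as.integer(intd > median(intd)) +
      0.4 * as.integer(mixz > median(mixz)) - 0.3 * dist + 1.5 * pr +
      0.2 * (ag == "adolescent")
    data.frame(pid = as.character(1:n), age_group = ag,
               school_id = as.character(school), distance_km = dist,
               prd = pr, res_density = resd, int_density = intd,
               mixed_use_raw = 0.5, mixed_use_z = mixz,
               acs_trips = 5L, acs_binary = rbinom(n, 1, plogis(eta)),
               flags = "", stringsAsFactors = FALSE)
  }
  drops <- vapply(1:10, function(s) {
    seq <- run_model_sequence(gen(s), vif_threshold = 1.3)
    identical(seq$dropped, "res_d")
  }, logical(1))
  expect_gte(mean(drops), 0.8)
  seq <- run_model_sequence(gen(1), vif_threshold = 1.3)
  expect_false("res_d" %in% seq$model2$child$coefficients$term)
  expect_true(all(c("int_d", "mix_d", "distance_km", "prd") %in%
                  seq$model2$adolescent$coefficients$term))
  ## single-stratum input errors
  rec1 <- gen(2); rec1$age_group <- "child"
  expect_error(run_model_sequence(rec1), "both age groups")
})
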