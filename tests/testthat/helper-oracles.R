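# Independent oracles and in-code fixtures shared across the suite.
# Each oracle deliberately takes a different computational route from the
# package implementation it checks.

# composite Simpson rule on a fine uniform grid
simpson <- function(f, a, b, n = 1e5) {
  if (n %% 2 == 1) n <- n + 1
  x <- seq(a, b, length.out = n + 1)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f(x)) * (b - a) / (3 * n)
}

# DSS oracle: Simpson integration of the capped/thresholded 4PL
dss_simpson <- function(bottom, top, ec50, hill, x_min, x_max,
                        t = 10, cap = 100, n = 1e5) {
  y <- function(x) bottom + (top - bottom) / (1 + 10^(hill * (log10(ec50) - x)))
  ybar <- function(x) pmin(y(x), cap)
  xs <- seq(x_min, x_max, length.out = 2001)
  if (max(ybar(xs)) > t) {
    return(100 * simpson(function(x) pmax(ybar(x) - t, 0), x_min, x_max, n) /
             ((100 - t) * (x_max - x_min)))
  }
  if (min(ybar(xs)) >= 0) return(0)
  if (max(ybar(xs)) < 0) {
    return(100 * simpson(ybar, x_min, x_max, n) / (100 * (x_max - x_min)))
  }
  0
}

# random 4PL curve within the fitting bounds, as an fpm_curve
random_curve <- function() {
  x_min <- log10(5e-4); x_max <- 1
  bottom <- runif(1, -40, 20)
  top <- bottom + runif(1, 5, 140)
  fpmdst:::new_curve(bottom = bottom, top = min(top, 150),
                     m = runif(1, x_min - 1, x_max + 1),
                     hill = runif(1, 0.3, 6), rss = 0, converged = TRUE,
                     x_min = x_min, x_max = x_max, n = 20L)
}

# Barnard oracle: direct double-loop enumeration of the extreme region,
# then a plain dbinom-product sweep over a fixed nuisance grid (no
# polynomial grouping, no refinement step)
barnard_oracle <- function(x1, n1, x2, n2, n_grid = 2000) {
  score <- function(a, b) {
    p1 <- a / n1; p2 <- b / n2; pp <- (a + b) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
    if (v <= 0) 0 else (p1 - p2) / sqrt(v)
  }
  z0 <- score(x1, x2)
  ext_a <- integer(0); ext_b <- integer(0)
  for (a in 0:n1) for (b in 0:n2) {
    z <- score(a, b)
    extreme <- abs(z) > abs(z0) + 1e-9 ||
      (abs(abs(z) - abs(z0)) <= 1e-9 && ((z0 >= 0 && z >= 0) || (z0 < 0 && z <= 0)))
    if (extreme) { ext_a <- c(ext_a, a); ext_b <- c(ext_b, b) }
  }
  grid <- seq(1 / (n_grid + 1), n_grid / (n_grid + 1), length.out = n_grid)
  max(vapply(grid, function(pi) {
    sum(dbinom(ext_a, n1, pi) * dbinom(ext_b, n2, pi))
  }, numeric(1)))
}

# exact signed-rank oracle: two-sided P by explicit loop over the 2^n sign
# vectors (bitmask route, unlike the implementation's matrix expansion)
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    v <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    if (abs(v - mu) >= abs(V - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# pairwise-concordance AUC oracle: explicit double loop
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Clopper-Pearson oracle: root-finding on the binomial tail equations
clopper_pearson_oracle <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (k == 0) 0 else
    uniroot(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low, high)
}

# grid + polish RSS oracle for the 4PL fit: for each (m, hill) on a grid the
# model is linear in (bottom, top), solved exactly; the grid optimum is then
# polished with L-BFGS-B (a different optimizer from the implementation)
fit_rss_oracle <- function(x, y, n_m = 120, n_h = 40) {
  x_min <- min(x); x_max <- max(x)
  best <- list(rss = Inf)
  for (m in seq(x_min - 1, x_max + 1, length.out = n_m)) {
    for (h in exp(seq(log(0.05), log(10), length.out = n_h))) {
      w <- 1 / (1 + 10^(h * (m - x)))
      fit <- stats::lm.fit(cbind(1 - w, w), y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) best <- list(rss = rss, m = m, h = h,
                                       bottom = fit$coefficients[1],
                                       top = fit$coefficients[2])
    }
  }
  obj <- function(p) {
    pr <- p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (p[3] - x)))
    sum((pr - y)^2)
  }
  pol <- stats::optim(c(best$bottom, best$top, best$m, best$h), obj,
                      method = "L-BFGS-B",
                      lower = c(-100, -100, x_min - 1, 1e-3),
                      upper = c(50, 150, x_max + 1, 10),
                      control = list(maxit = 500, factr = 1e3))
  min(best$rss, pol$value)
}

# hand-built miniature plate: duplicate series for one or more drugs plus
# control wells with the stated luminescence values
make_mini_plate <- function(drug_y, neg = rep(1e5, 4), pos = rep(2e3, 4),
                            conc = 10^seq(log10(5e-4), 1, length.out = 10),
                            mu_n = 1e5, mu_p = 2e3, plate_id = "mini",
                            patient_id = "pt1", ...) {
  rows <- list(); k <- 0
  addr <- paste0(rep(LETTERS[1:16], each = 24), rep(1:24, times = 16))
  take <- function(n) { w <- addr[(k + 1):(k + n)]; k <<- k + n; w }
  for (id in names(drug_y)) {
    y <- drug_y[[id]]  # one inhibition value per conc, duplicated
    rows[[id]] <- data.frame(
      well = take(2 * length(conc)), content = "drug_dose", drug_id = id,
      concentration_uM = rep(conc, each = 2), replicate = rep(1:2, length(conc)),
      rlu = mu_n - (mu_n - mu_p) * rep(y, each = 2) / 100,
      stringsAsFactors = FALSE)
  }
  rows$ctrl <- data.frame(
    well = take(length(neg) + length(pos)),
    content = rep(c("negative_control", "positive_control"), c(length(neg), length(pos))),
    drug_id = NA, concentration_uM = NA, replicate = 1,
    rlu = c(neg, pos), stringsAsFactors = FALSE)
  fpm_plate(do.call(rbind, rows), plate_id = plate_id, patient_id = patient_id, ...)
}

table2_outcomes <- function() {
  read_outcomes(system.file("extdata", "outcomes_table2.csv", package = "fpmdst"))
}
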