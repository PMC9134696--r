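# Independent straight-line reimplementation of the capacity-to-pay CHE
# chain, written with explicit loops and a hand-rolled interpolated
# percentile. Deliberately shares no code with the package: it is the oracle
# the vectorized implementation is judged against.
oracle_che <- function(food, exp, oop, hhsize, beta = 0.56, band = c(45, 55),
                       threshold = 0.4, w = rep(1, length(food))) {
  n <- length(food)
  fe <- eqs <- eqf <- numeric(n)
  for (i in seq_len(n)) {
    fe[i] <- food[i] / exp[i]
    eqs[i] <- hhsize[i]^beta
    eqf[i] <- food[i] / eqs[i]
  }
  pct <- function(x, p) { # linear interpolation between order statistics
    s <- sort(x)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  f_lo <- pct(fe, band[1] / 100)
  f_hi <- pct(fe, band[2] / 100)
  sel <- which(fe > f_lo & fe < f_hi)
  if (length(sel) == 0) sel <- which(fe >= f_lo & fe <= f_hi)
  pl <- sum(w[sel] * eqf[sel]) / sum(w[sel])
  se <- ctp <- numeric(n)
  oopctp <- rep(NA_real_, n)
  cata <- integer(n)
  for (i in seq_len(n)) {
    se[i] <- pl * eqs[i]
    ctp[i] <- if (se[i] <= food[i]) exp[i] - se[i] else exp[i] - food[i]
    if (ctp[i] > 0) {
      oopctp[i] <- oop[i] / ctp[i]
      cata[i] <- as.integer(oopctp[i] >= threshold)
    } else {
      cata[i] <- as.integer(oop[i] > 0)
    }
  }
  list(food_share = fe, eqsize = eqs, eqfood = eqf, pl = pl, se = se,
       ctp = ctp, oopctp = oopctp, cata = cata)
}

# Random toy household table exercising both capacity-to-pay branches and the
# degenerate food > exp case.
toy_households <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    household_id = sprintf("t%05d", seq_len(n)),
    hhsize = sample(1:6, n, replace = TRUE),
    food_month = runif(n, 50, 1500),
    exp_month = runif(n, 100, 6000),
    oop_month = round(rexp(n, 1 / 300), 2) * rbinom(n, 1, 0.7)
  )
}

# Hand-built raw survey (pre-deflation layout) for preprocessing tests.
toy_raw_survey <- function(households, members) {
  structure(list(households = households, members = members,
                 truth = NULL, config = NULL),
            class = "raw_survey")
}
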