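# Independent reference implementations used as oracles. These are written
# directly from the model definitions and numeric conventions, without
# calling the package's own building blocks, so agreement is meaningful.

# Literal hour-by-hour run of the kinetic model: precursor/chill recursion
# followed by weighted GDH accumulation. Returns full trajectories and the
# (1-based, integer) bloom hour.
oracle_engine <- function(temp, par) {
  n <- length(temp)
  x <- 0; y <- 0; z <- 0
  ytr <- numeric(n); ztr <- numeric(n)
  bloom <- NA_integer_
  for (i in seq_len(n)) {
    TK <- temp[i] + 273.15
    xs <- (par[["A0"]] / par[["A1"]]) * exp(-(par[["E0"]] - par[["E1"]]) / TK)
    k1 <- par[["A1"]] * exp(-par[["E1"]] / TK)
    xstar <- xs - (xs - x) * exp(-k1)
    if (xstar >= 1) {
      sig <- 1 / (1 + exp(-par[["slope"]] * (temp[i] - par[["Tf"]])))
      delta <- xstar * sig
      x <- xstar - delta
      y <- y + delta
    } else {
      x <- xstar
    }
    Tt <- temp[i]
    g <- if (Tt <= par[["Tb"]] || Tt >= par[["Tc"]]) 0
    else if (Tt <= par[["Tu"]])
      (par[["Tu"]] - par[["Tb"]]) / 2 *
        (1 + cos(pi + pi * (Tt - par[["Tb"]]) / (par[["Tu"]] - par[["Tb"]])))
    else
      (par[["Tu"]] - par[["Tb"]]) *
        (1 + cos(pi / 2 + pi / 2 * (Tt - par[["Tu"]]) / (par[["Tc"]] - par[["Tu"]])))
    w <- min(1, exp(par[["s1"]] * (y - par[["yc"]])))
    z <- z + g * w
    ytr[i] <- y; ztr[i] <- z
    if (is.na(bloom) && z >= par[["zc"]]) bloom <- i
  }
  list(y = ytr, z = ztr, bloom = bloom)
}

# Linear-interpolation quantile written out by hand (order statistic h-index).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Brute-force IQR fence filter.
oracle_iqr <- function(values) {
  q1 <- oracle_quantile(values, 0.25)
  q3 <- oracle_quantile(values, 0.75)
  iqr <- q3 - q1
  keep <- values >= q1 - 1.5 * iqr & values <= q3 + 1.5 * iqr
  list(kept = values[keep], removed = values[!keep])
}

# Exhaustive optimal 1-D partition: enumerate every way of cutting the sorted
# values into k contiguous classes and pick the minimum within-class SS
# (earliest cut vector on ties).
oracle_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  wss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(list(breaks = x[n], wss = wss(x)))
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- NULL; best_w <- Inf
  for (cc in cuts) {
    bounds <- c(0, cc, n)
    w <- sum(vapply(seq_len(k), function(m)
      wss(x[(bounds[m] + 1):bounds[m + 1]]), numeric(1)))
    if (w < best_w - 1e-12) {
      best_w <- w
      best <- x[c(cc, n)]
    }
  }
  list(breaks = best, wss = best_w)
}

# Draw a random valid parameter vector within the default box (respecting the
# Tb < Tu < Tc ordering).
random_params <- function() {
  b <- phenoflex_bounds()
  repeat {
    p <- b$lower + runif(12) * (b$upper - b$lower)
    names(p) <- names(b$lower)
    if (p[["Tb"]] < p[["Tu"]] && p[["Tu"]] < p[["Tc"]] &&
        p[["yc"]] > 0 && p[["zc"]] > 0)
      return(as_phenoflex_params(p))
  }
}

# Solar declination by an independent standard approximation, for checking
# the day-length model.
oracle_daylength <- function(lat, doy) {
  decl <- -23.44 * cos(2 * pi / 365 * (doy + 10)) * pi / 180
  latr <- lat * pi / 180
  ha <- acos(pmin(1, pmax(-1, -tan(latr) * tan(decl))))
  24 * ha / pi
}
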