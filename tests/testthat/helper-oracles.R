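# Independent reference implementations ("oracles") used to check the
# package's algorithms. Written as naive explicit loops on purpose: they
# share no code with the implementations they verify.

# valley-seeking threshold, step by step: smooth with an explicit loop until
# exactly two local maxima remain (a plateau of equal values that stands
# above both sides is one maximum), then scan the open interval between them
# for the lowest minimal bin
oracle_find_max_runs <- function(v) {
  n <- length(v)
  runs <- list()
  start <- 1L
  for (i in seq_len(n)) {
    if (i == n || v[i + 1L] != v[i]) {
      runs[[length(runs) + 1L]] <- c(start, i, v[i])
      start <- i + 1L
    }
  }
  maxima <- list()
  for (j in seq_along(runs)) {
    above_left <- j == 1L || runs[[j]][3] > runs[[j - 1L]][3]
    above_right <- j == length(runs) || runs[[j]][3] > runs[[j + 1L]][3]
    if (above_left && above_right) maxima[[length(maxima) + 1L]] <- runs[[j]]
  }
  maxima
}

oracle_threshold_minimum <- function(counts, max_iter = 10000L) {
  x <- as.numeric(counts)
  n <- length(x)
  it <- 0L
  repeat {
    maxima <- oracle_find_max_runs(x)
    if (length(maxima) == 2L) break
    if (it >= max_iter) {
      return(NULL)
    }
    s <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - 1L)
      hi <- min(n, i + 1L)
      s[i] <- mean(x[lo:hi])
    }
    x <- s
    it <- it + 1L
  }
  best <- NA_integer_
  best_val <- Inf
  for (i in (maxima[[1]][2] + 1L):(maxima[[2]][1] - 1L)) {
    if (x[i] < best_val) {
      best_val <- x[i]
      best <- i
    }
  }
  best - 1L
}

# check the intermeans fixed-point property of a candidate threshold t by
# direct evaluation: t must reproduce itself under the update rule
oracle_isodata_is_fixed_point <- function(counts, t) {
  lev <- 0:255
  lo <- lev <= t
  if (sum(counts[lo]) == 0 || sum(counts[!lo]) == 0) {
    return(FALSE)
  }
  m1 <- sum(counts[lo] * lev[lo]) / sum(counts[lo])
  m2 <- sum(counts[!lo] * lev[!lo]) / sum(counts[!lo])
  ceiling((m1 + m2) / 2 - 0.5) == t
}

# brute-force per-pixel mean inverted intensity, as a percentage
oracle_dabwt_per_pixel <- function(values) {
  total <- 0
  for (v in values) total <- total + (255 - v) / 255
  100 * total / length(values)
}

# random 256-bin histogram with at least two occupied levels
random_histogram <- function() {
  k <- sample(2:20, 1)
  h <- integer(256)
  levels <- sample(0:255, k)
  h[levels + 1] <- sample(1:500, k, replace = TRUE)
  h
}

# random histogram made of two well-separated Gaussian bumps
random_bimodal_histogram <- function() {
  m1 <- sample(20:90, 1)
  m2 <- sample(150:235, 1)
  s1 <- runif(1, 3, 12)
  s2 <- runif(1, 3, 12)
  w1 <- runif(1, 0.2, 0.8)
  n <- 5000
  v <- c(
    round(rnorm(round(n * w1), m1, s1)),
    round(rnorm(n - round(n * w1), m2, s2))
  )
  v <- v[v >= 0 & v <= 255]
  tabulate(v + 1L, nbins = 256L)
}

# small random 8-bit RGB test image
random_rgb_image <- function(h = 16, w = 16) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}
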