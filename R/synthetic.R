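#' Predictor sampling distributions
#'
#' Building blocks of [synthetic_spec()]: per-predictor sampling
#' distributions for synthetic training data. `dist_normal` is truncated to
#' the predictor's declared domain by inverse-CDF sampling, so every draw
#' stays inside the domain.
#'
#' @param lo,hi Uniform bounds.
#' @param mu,sigma Normal location and scale (`sigma > 0`).
#' @param p Bernoulli success probability.
#' @param levels,probs Categorical levels and their probabilities (summing
#'   to 1).
#' @name distributions
NULL

new_dist <- function(family, ...) {
  structure(c(list(family = family), list(...)), class = "riskviz_dist")
}

#' @rdname distributions
#' @export
dist_uniform <- function(lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi), lo < hi)
  new_dist("uniform", lo = lo, hi = hi)
}

#' @rdname distributions
#' @export
dist_normal <- function(mu, sigma) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma > 0)
  new_dist("normal", mu = mu, sigma = sigma)
}

#' @rdname distributions
#' @export
dist_bernoulli <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  new_dist("bernoulli", p = p)
}

#' @rdname distributions
#' @export
dist_categorical <- function(levels, probs) {
  levels <- as.character(levels)
  probs <- as.numeric(probs)
  stopifnot(length(levels) == length(probs), all(probs >= 0),
            abs(sum(probs) - 1) < 1e-8)
  new_dist("categorical", levels = levels, probs = probs)
}

#' Synthetic training-data specification
#'
#' Pairs one [distributions] object with every model predictor, a sample
#' size and a mandatory seed: there is no implicit global randomness, so the
#' same spec always generates bit-identical data.
#'
#' @param distributions Named list: predictor name -> distribution.
#' @param n Number of rows, >= 1.
#' @param seed Integer RNG seed (required).
#' @return A `riskviz_synth_spec`.
#' @export
synthetic_spec <- function(distributions, n, seed) {
  stopifnot(is.list(distributions), length(distributions) > 0L,
            !is.null(names(distributions)))
  for (d in distributions) stopifnot(inherits(d, "riskviz_dist"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is required", call. = FALSE)
  structure(list(distributions = distributions, n = n,
                 seed = as.integer(seed)),
            class = "riskviz_synth_spec")
}

#' Default synthetic spec for the bundled artificial model
#'
#' Fixed, documented sampling conditions for reproducible training
#' summaries: age ~ uniform(30, 90), biomarker ~ uniform(0, 200),
#' gender ~ Bernoulli(0.5), smoker ~ Bernoulli(0.3).
#'
#' @param n Number of rows (default 1000).
#' @param seed RNG seed (default 20150715).
#' @return A [synthetic_spec()].
#' @export
default_artificial_spec <- function(n = 1000L, seed = 20150715L) {
  synthetic_spec(list(
    gender = dist_bernoulli(0.5),
    age = dist_uniform(30, 90),
    smoker = dist_bernoulli(0.3),
    biomarker = dist_uniform(0, 200)), n = n, seed = seed)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic training dataset
#'
#' Draws `spec$n` rows, one column per distribution in spec order,
#' reproducibly for a fixed seed (the global RNG state is restored
#' afterwards). When a `model` is supplied, domains are checked: a
#' distribution whose support falls outside its predictor's declared domain
#' is rejected.
#'
#' @param spec A [synthetic_spec()].
#' @param model Optional [risk_model()] to validate domains against.
#' @return A data frame with `spec$n` rows.
#' @export
generate_training_data <- function(spec, model = NULL) {
  stopifnot(inherits(spec, "riskviz_synth_spec"))
  if (!is.null(model)) check_support(spec, model)
  doms <- lapply(names(spec$distributions), function(nm) {
    p <- if (is.null(model)) NULL else model$predictors[[nm]]
    if (!is.null(p) && p$kind == "continuous") p$domain else NULL
  })
  cols <- with_local_seed(spec$seed, {
    lapply(seq_along(spec$distributions), function(i)
      draw_dist(spec$distributions[[i]], spec$n, domain = doms[[i]]))
  })
  names(cols) <- names(spec$distributions)
  as.data.frame(cols, optional = TRUE, check.names = FALSE)
}

draw_dist <- function(d, n, domain = NULL) {
  switch(d$family,
    uniform = stats::runif(n, d$lo, d$hi),
    normal = {
      lo <- if (is.null(domain)) -Inf else domain[1L]
      hi <- if (is.null(domain)) Inf else domain[2L]
      plo <- stats::pnorm(lo, d$mu, d$sigma)
      phi <- stats::pnorm(hi, d$mu, d$sigma)
      stats::qnorm(stats::runif(n, plo, phi), d$mu, d$sigma)
    },
    bernoulli = stats::rbinom(n, 1L, d$p),
    categorical = sample(d$levels, n, replace = TRUE, prob = d$probs))
}

check_support <- function(spec, model) {
  for (nm in names(spec$distributions)) {
    p <- model$predictors[[nm]]
    if (is.null(p)) next
    d <- spec$distributions[[nm]]
    ok <- switch(d$family,
      uniform = p$kind == "continuous" && d$lo >= p$domain[1L] &&
        d$hi <= p$domain[2L],
      normal = p$kind == "continuous",
      bernoulli = p$kind != "continuous" &&
        all(c("0", "1") %in% p$domain),
      categorical = p$kind != "continuous" &&
        all(d$levels %in% p$domain))
    if (!ok)
      stop("distribution for '", nm, "' has support outside the ",
           "predictor's declared domain", call. = FALSE)
  }
  invisible(TRUE)
}
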