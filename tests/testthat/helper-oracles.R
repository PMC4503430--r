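# Independent oracles: plain-arithmetic evaluators that never touch the
# package's transformation/term machinery, used to cross-check it.

# the artificial logistic model, written out symbolically term by term
oracle_artificial_z <- function(gender, age, smoker, biomarker) {
  -1 +
    (-2) * gender +
    0.005 * (age - 60)^2 +
    3 * smoker +
    (-0.02) * biomarker +
    0.3 * gender * ((age - 60) / 10)^3 +
    (-2.5) * gender * smoker +
    0.00005 * (age - 60)^2 * biomarker
}

oracle_logistic <- function(z) 1 / (1 + exp(-z))

# per-term raw contributions of the artificial model for a data frame of
# patients; column order matches the builtin term order
oracle_artificial_terms <- function(d) {
  cbind(
    gender = -2 * d$gender,
    age = 0.005 * (d$age - 60)^2,
    smoker = 3 * d$smoker,
    biomarker = -0.02 * d$biomarker,
    `gender:age` = 0.3 * d$gender * ((d$age - 60) / 10)^3,
    `gender:smoker` = -2.5 * d$gender * d$smoker,
    `age:biomarker` = 0.00005 * (d$age - 60)^2 * d$biomarker)
}

# hand-summed score lookups straight off the printed tables
oracle_ic_points <- list(
  sex = function(v) if (v == "male") 3 else 0,
  age = function(v) {
    edges <- c(45, 50, 55, 60, 65, 70, 75, 80, 85)
    findInterval(v, edges) - 1
  },
  cholesterol = function(v) {
    if (v < 170) 0 else if (v <= 209) 1 else if (v <= 249) 2
    else if (v <= 289) 3 else 4
  },
  blood_pressure = function(v) c(normal = 0, `high normal` = 1,
                                 `stage 1` = 2, `stage 2+` = 4)[[v]],
  cigarettes = function(v) {
    if (v == 0) 0 else if (v <= 5) 1 else if (v <= 10) 2
    else if (v <= 20) 3 else 4
  },
  diabetes = function(v) if (v == "yes") 5 else 0,
  chd = function(v) if (v == "yes") 5 else 0)

oracle_ic_score <- function(patient) {
  sum(vapply(names(oracle_ic_points),
             function(nm) oracle_ic_points[[nm]](patient[[nm]]),
             numeric(1)))
}

# random artificial-model patients inside the declared domains
random_artificial_patients <- function(n, seed) {
  set.seed(seed)
  data.frame(gender = rbinom(n, 1, 0.5),
             age = runif(n, 30, 90),
             smoker = rbinom(n, 1, 0.5),
             biomarker = runif(n, 0, 200))
}

# a small random linear model plus an independent closure evaluating it
random_linear_model <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  coefs <- round(rnorm(k), 3)
  beta0 <- round(rnorm(1), 3)
  nms <- paste0("x", seq_len(k))
  shifts <- round(runif(k, -1, 1), 2)
  pows <- sample(1:2, k, replace = TRUE)
  model <- risk_model(
    intercept = beta0,
    predictors = lapply(nms, function(nm)
      predictor(nm, "continuous", c(-10, 10))),
    terms = lapply(seq_len(k), function(i)
      effect_term(nms[i], nms[i], coefs[i],
                  transform_shifted_power(shifts[i], pows[i]))),
    link = link_logistic())
  oracle <- function(vals)
    beta0 + sum(coefs * (unlist(vals[nms]) - shifts)^pows)
  list(model = model, oracle = oracle, names = nms)
}

# turn a printed "range or level" cell into one probe value inside it
literal_probe <- function(cell) {
  cell <- trimws(cell)
  if (grepl("^<", cell)) return(as.numeric(sub("^<", "", cell)) - 1)
  if (grepl("^>", cell)) return(as.numeric(sub("^>", "", cell)) + 1)
  if (grepl("^[0-9]+-[0-9]+$", cell))
    return(as.numeric(strsplit(cell, "-")[[1]][1]))
  num <- suppressWarnings(as.numeric(cell))
  if (!is.na(num)) num else cell
}

fixture_path <- function(...) {
  system.file("extdata", ..., package = "riskviz", mustWork = TRUE)
}
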