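# Shared fixtures, built in code at test time.

GP_COLS <- paste0("GP", 1:46)

# Random closed 46-part composition (strictly positive).
random_composition <- function(n = 1, min = 0.05, max = 8) {
  m <- matrix(runif(n * 46, min, max), n, 46, dimnames = list(NULL, GP_COLS))
  m <- t(apply(m, 1, function(r) 100 * r / sum(r)))
  if (n == 1) m[1, ] else m
}

# Small synthetic composition cohort with a planted two-part log-ratio
# signal: logit(P(y=1)) = beta * ln(x_a / x_b), parts otherwise iid
# log-normal before closure.
planted_pair_cohort <- function(n = 400, p = 12, a = 3, b = 7, beta = 2,
                                sdlog = 0.4) {
  labels <- sprintf("P%02d", seq_len(p))
  x <- matrix(rlnorm(n * p, 0, sdlog), n, p, dimnames = list(NULL, labels))
  x <- t(apply(x, 1, function(r) 100 * r / sum(r)))
  eta <- beta * log(x[, a] / x[, b])
  eta <- eta - mean(eta)
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y, a = labels[a], b = labels[b])
}

# Trait formula table re-stated literally, as printed strings, for the
# brute-force oracle: independent of the package's coefficient matrix.
trait_formula_strings <- function() {
  c(
    S0 = "GP1-15",
    S1 = "GP16-23 + GP30",
    S2 = "GP24-29 + GP31",
    S3 = "GP32-40",
    S4 = "GP41-46",
    G0 = "GP1-2 + GP4-5 + (GP6/2) + (GP12/2)",
    G1 = "GP3 + GP7-10 + (GP12/2) + GP16-18 + (GP21/2)",
    G2 = "GP13-15 + GP19 + GP20 + (GP21/2) + GP22-28",
    G3 = "GP29 + GP31-37",
    G4 = "GP30 + GP38-46",
    A1 = "GP1-3 + (GP12/2) + (GP21/2)",
    A2 = "GP4-5 + (GP6/2) + GP7-10 + (GP12/2) + GP13-20 + (GP21/2) + GP22-28",
    A3 = "GP29 + GP31-37",
    A4 = "GP30 + GP38-46",
    OM = "(GP6/2) + GP11",
    CF = "GP2 + GP5 + (GP6/2) + GP8-10 + GP14-15 + GP17-18 + GP22-23 + GP27-28 + GP36 + (GP44/2)",
    OF = "GP37 + GP40 + (GP41/3) + GP45 + (GP46/3)"
  )
}

# Brute-force trait evaluator: parses each formula string term by term.
# Terms are "GPa", "GPa-b" (range, coefficient 1) or "(GPa/k)".
oracle_trait <- function(gp, formula) {
  total <- 0
  for (term in strsplit(formula, "+", fixed = TRUE)[[1]]) {
    term <- gsub("[ ()]", "", term)
    if (grepl("/", term, fixed = TRUE)) {
      parts <- strsplit(term, "/", fixed = TRUE)[[1]]
      idx <- as.integer(sub("GP", "", parts[1]))
      total <- total + gp[idx] / as.numeric(parts[2])
    } else if (grepl("-", term, fixed = TRUE)) {
      rng <- as.integer(sub("GP", "", strsplit(term, "-", fixed = TRUE)[[1]]))
      total <- total + sum(gp[rng[1]:rng[2]])
    } else {
      total <- total + gp[as.integer(sub("GP", "", term))]
    }
  }
  unname(total)
}

small_male_spec <- function(n = 40, seed = 1) {
  default_cohort_spec("M", c("non-risk" = n, risk = n), seed = seed)
}
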