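# Shared helpers: an independent OLS oracle and small random-table factories.

# Textbook normal-equations oracle: solve X'X beta = X'y directly.
# Independent of the package's running-sums implementation.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  a <- beta[1L]; b <- beta[2L]
  r <- y - X %*% beta
  q <- sum(r^2)
  s2 <- q / (length(x) - 2)
  sxx <- sum((x - mean(x))^2)
  list(a = a, b = b, Q = q, s2 = s2, Sxx = sxx, Vb = s2 / sxx)
}

# Random small dose-effect table with >= 2 dose levels.
random_table <- function(seed, n_levels = 3, n_per = 2) {
  set.seed(seed)
  doses <- sort(10^runif(n_levels, -2, 1))
  dose <- rep(doses, each = n_per)
  y <- rnorm(length(dose), 20 + 15 * log10(dose), 20)
  dose_effect_table(dose, y, regimen = "random")
}

# Paper-like single-drug specs (Table-1 / Table-2 geometry).
spec_paperA <- function(n = 12, sigma = 25.6)
  sim_spec(a = 20.9, b = 16.3, sigma = sigma,
           dose_levels = c(0.1, 0.4, 1, 2, 6), n_per_dose = n, regimen = "simA")
spec_paperB <- function(n = 12, sigma = 25)
  sim_spec(a = 55.9, b = 22.4, sigma = sigma,
           dose_levels = c(0.01, 0.03, 0.1, 0.3, 0.5), n_per_dose = n,
           regimen = "simB")

# Equal-potency null: both drugs have ED20 = 1 nmol/site, so the additive
# variance transport f^2 V(A) + (1-f)^2 V(B) is exact (see methods vignette).
null_combo_spec <- function(seed, n = 60)
  combo_sim_spec(
    sim_spec(a = 20, b = 16, sigma = 25, dose_levels = c(0.1, 0.4, 1, 2, 6),
             n_per_dose = n, regimen = "nullA"),
    sim_spec(a = 20, b = 22, sigma = 25, dose_levels = c(0.1, 0.4, 1, 2, 6),
             n_per_dose = n, regimen = "nullB"),
    alpha_true = 1, seed = seed)

# Paper-like synergistic combination (effect size ~ the fixtures' index).
synergy_combo_spec <- function(seed, alpha_true = 0.07, n = 12)
  combo_sim_spec(spec_paperA(n), spec_paperB(n), alpha_true = alpha_true,
                 seed = seed)
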