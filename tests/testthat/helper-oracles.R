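# Independent oracles used across tests.

# Gene-dropping Monte Carlo estimate of the additive relationship matrix:
# founders get unique allele labels, alleles are transmitted with equal
# probability, and relationships are estimated from identity-by-descent
# frequencies (A_ij = 2 * kinship_ij; A_ii = 1 + P(i's alleles are IBD)).
# Requires parents to precede children and parentage to be all-or-none.
gene_drop_relationship <- function(ped, n_rep = 1e5, seed = 1) {
  set.seed(seed)
  id <- ped$id
  n <- length(id)
  fa <- match(ped$father, id)
  mo <- match(ped$mother, id)
  a1 <- matrix(0L, n_rep, n)
  a2 <- matrix(0L, n_rep, n)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      a1[, i] <- 2L * i - 1L
      a2[, i] <- 2L * i
    } else {
      pick <- stats::runif(n_rep) < 0.5
      a1[, i] <- ifelse(pick, a1[, fa[i]], a2[, fa[i]])
      pick <- stats::runif(n_rep) < 0.5
      a2[, i] <- ifelse(pick, a1[, mo[i]], a2[, mo[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        A[i, i] <- 1 + mean(a1[, i] == a2[, i])
      } else {
        phi <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
                (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
        A[i, j] <- A[j, i] <- 2 * mean(phi)
      }
    }
  }
  A
}

# Closed-form generalized least squares with a fully known covariance.
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  G <- crossprod(X, Vi %*% X)
  beta <- solve(G, crossprod(X, Vi %*% y))
  list(beta = drop(beta), se = sqrt(diag(solve(G))))
}

# Two hand-built pedigrees used in several tests.
trio_pedigree <- function() {
  data.frame(id = c("dad", "mom", "kid"),
             father = c("0", "0", "dad"),
             mother = c("0", "0", "mom"),
             sex = c("M", "F", "M"),
             stringsAsFactors = FALSE)
}

# Full sibs who mate (inbred offspring): textbook A values.
inbred_pedigree <- function() {
  data.frame(id = c("gf", "gm", "s1", "s2", "inb"),
             father = c("0", "0", "gf", "gf", "s1"),
             mother = c("0", "0", "gm", "gm", "s2"),
             sex = c("M", "F", "M", "F", "M"),
             stringsAsFactors = FALSE)
}

# Small shared simulation, computed once per test run.
.fixture_env <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(n_families = 10, seed = 424242)
    .fixture_env$sim <- simulate_cohort(cfg)
  }
  .fixture_env$sim
}

# Full-scale study population (default config), shared by the acceptance
# experiments: the pedigree and relationship matrix stay fixed while
# covariates, exposures and outcomes are redrawn per replicate.
full_population <- function() {
  if (is.null(.fixture_env$pop)) {
    cfg <- sim_config(seed = 1234)
    ped <- generate_pedigree(cfg)
    A <- kinship_matrix(ped)
    .fixture_env$pop <- list(cfg = cfg, ped = ped, A = A,
                             ke = kinship_eigen(A))
  }
  .fixture_env$pop
}

replicate_study <- function(pop, seed, lag_weights = NULL) {
  cfg <- pop$cfg
  cfg$seed <- seed
  if (!is.null(lag_weights)) cfg$true_lag_weights <- lag_weights
  cov <- simulate_covariates(pop$ped, cfg)
  panel <- simulate_exposures(pop$ped, cfg)
  coh <- add_vascular_metrics(
    simulate_outcomes(pop$ped, panel, cov, cfg, A = pop$A))
  list(cohort = coh, panel = panel)
}
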