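# Independent oracles and shared fixtures. The brute-force Spearman oracle
# enumerates rank permutations with its own recursive generator and computes
# rho with stats::cor, sharing no code with the package implementation.

brute_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in brute_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

brute_spearman_p <- function(x, y, alternative = "two.sided") {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  rhos <- vapply(brute_perms(ry), function(py) stats::cor(rx, py), numeric(1))
  eps <- 1e-8
  p <- switch(alternative,
    two.sided = mean(abs(rhos) >= abs(rho_obs) - eps),
    greater = mean(rhos >= rho_obs - eps),
    less = mean(rhos <= rho_obs + eps)
  )
  list(rho = rho_obs, p = p)
}

# canonical schedule fixtures
sched_identity <- 0:20
sched_tent <- c(0:10, 9:0)              # peak 10, falls back to 0
sched_zeros <- rep(0L, 21)
sched_const20 <- rep(20L, 21)

# per-sex genotype counts of the reference cohort
ref_oxtr_women <- c(AA = 18, GA = 38, GG = 48)
ref_oxtr_men <- c(AA = 9, GA = 29, GG = 40)
ref_rs3_women <- c("Long/Long" = 29, "Short/Long" = 42, "Short/Short" = 35)
ref_rs3_men <- c("Long/Long" = 13, "Short/Long" = 38, "Short/Short" = 28)

# strategy-by-sex counts reconstructed from the reported percentage distribution
ref_strategy_by_sex <- cbind(women = c(CC = 48, HS = 13, FR = 10, OT = 36),
                       men = c(CC = 44, HS = 9, FR = 8, OT = 20))

make_subject_row <- function(id, sex, uninformed, schedule,
                             maoa = c(3.5, 3.5), oxtr = c("G", "G"),
                             rs3 = c(335L, 345L)) {
  sched <- as.list(setNames(as.integer(schedule), paste0("c", 0:20)))
  c(list(id = id, sex = sex, uninformed = as.integer(uninformed)), sched,
    list(maoa_a1 = maoa[1], maoa_a2 = if (sex == "male") NA_real_ else maoa[2],
         oxtr_a1 = oxtr[1], oxtr_a2 = oxtr[2],
         rs3_a1_bp = rs3[1], rs3_a2_bp = rs3[2]))
}

make_subject_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
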