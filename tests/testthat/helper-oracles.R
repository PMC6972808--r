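# Builders and independent oracles used across the suite.

# Compact genotype builder: each argument after biotype is a named list of
# locus -> allele vector; unnamed loci default to a fixed diploid hybrid
# base genotype (eos + neogaeus haplome at both-genomes loci).
base_hybrid_alleles <- function() {
  list(`Seat412` = c(100L, 200L), `Ca-12` = c(102L, 202L),
       `Pho-60` = 150L, `Pho-1` = 152L, `Pho-2` = 154L,
       `Rhca-20` = c(104L, 204L))
}

make_hybrids <- function(..., site = "S1", biotype = "HYB") {
  mods <- list(...)
  n <- length(mods)
  alleles <- lapply(mods, function(m) {
    a <- base_hybrid_alleles()
    for (nm in names(m)) a[[nm]] <- m[[nm]]
    a
  })
  genotype_table(sprintf("i%02d", seq_len(n)), rep(site, n),
                 rep(biotype, n), alleles)
}

# Freeman-Halton exact test by full enumeration of margin-fixed r x 2 tables:
# p = sum of probabilities of all tables no more probable than the observed.
fisher_rx2_enum <- function(tab) {
  tab <- as.matrix(tab)
  r <- nrow(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  log_p_table <- function(first_col) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(first_col)) - sum(lfactorial(rs - first_col))
  }
  # enumerate first-column entries row by row
  grid <- expand.grid(lapply(seq_len(r), function(i) 0:min(rs[i], cs[1])))
  keep <- rowSums(grid) == cs[1]
  lp_obs <- log_p_table(tab[, 1])
  total <- 0
  for (k in which(keep)) {
    lp <- log_p_table(as.numeric(grid[k, ]))
    if (lp <= lp_obs + 1e-12) total <- total + exp(lp)
  }
  total
}

# Exact Markov-chain oracle for single-deme clonal Wright-Fisher drift:
# expected number of distinct lineages after `gens` generations starting
# from the count vector `init` (population size N = sum(init)).
wf_expected_distinct <- function(init, gens) {
  N <- sum(init)
  K <- length(init)
  states <- as.matrix(expand.grid(rep(list(0:N), K)))
  states <- states[rowSums(states) == N, , drop = FALSE]
  key <- apply(states, 1, paste, collapse = ",")
  trans <- matrix(0, nrow(states), nrow(states))
  for (i in seq_len(nrow(states))) {
    p <- states[i, ] / N
    for (j in seq_len(nrow(states))) {
      trans[i, j] <- stats::dmultinom(states[j, ], prob = p)
    }
  }
  v <- as.numeric(key == paste(init, collapse = ","))
  for (g in seq_len(gens)) v <- as.numeric(v %*% trans)
  sum(v * rowSums(states > 0))
}

# Closed-form rarefaction expectation (hypergeometric inclusion).
rarefaction_expect <- function(counts, n) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}
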