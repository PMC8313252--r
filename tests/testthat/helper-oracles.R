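# Independent oracles used across test files. These deliberately avoid the
# package's own orbit/flux code paths.

# all subsets of {1..6} at a level, as sorted integer vectors
oracle_subsets <- function(level) {
  if (level == 0) return(list(integer(0)))
  utils::combn(6, level, simplify = FALSE)
}

# brute-force mirror map, written independently of the package
oracle_mirror <- function(s) {
  out <- integer(length(s))
  for (i in seq_along(s)) {
    out[i] <- switch(s[i], 3L, 2L, 1L, 6L, 5L, 4L)
  }
  sort(out)
}

# brute-force orbit partition at one level: list of orbits, each a sorted
# character vector of member keys
oracle_orbits <- function(level) {
  sets <- oracle_subsets(level)
  keys <- vapply(sets, paste, "", collapse = "")
  seen <- character(0)
  orbits <- list()
  for (i in seq_along(sets)) {
    if (keys[i] %in% seen) next
    mk <- paste(oracle_mirror(sets[[i]]), collapse = "")
    orbit <- sort(unique(c(keys[i], mk)))
    orbits[[length(orbits) + 1L]] <- orbit
    seen <- c(seen, orbit)
  }
  orbits
}

# count distinct InsP6 -> InsP0 maximal paths by dynamic programming over
# subset bitmasks (independent of the package's graph structure)
oracle_path_count <- function() {
  paths <- numeric(64)
  paths[1] <- 1 # empty set, bitmask 0 -> index 1
  for (mask in 1:63) {
    total <- 0
    for (p in 0:5) {
      if (bitwAnd(mask, bitwShiftL(1L, p)) != 0) {
        total <- total + paths[bitwAnd(mask, bitwNot(bitwShiftL(1L, p))) + 1]
      }
    }
    paths[mask + 1] <- total
  }
  paths[64]
}

# random normalized profile over a subset of assignable classes
random_profile <- function(classes, n_active = length(classes),
                           min_fraction = 0.03) {
  stopifnot(n_active * min_fraction < 1)
  active <- sample(classes, n_active)
  u <- stats::runif(n_active)
  fr <- min_fraction + u / sum(u) * (1 - n_active * min_fraction)
  out <- tibble::tibble(class = classes,
                        amount = ifelse(classes %in% active,
                                        fr[match(classes, active)], 0))
  out$amount[is.na(out$amount)] <- 0
  out$mole_fraction <- out$amount / sum(out$amount)
  out
}

# run the full recovery pipeline on a chromatogram
requantify <- function(chrom, rt) {
  pk <- detect_peaks(chrom)
  pk <- integrate_and_assign(pk, chrom, rt)
  suppressWarnings(quantify(pk))
}

# random community for conservation property tests
random_community <- function() {
  n_enz <- sample(1:3, 1)
  enzymes <- lapply(seq_len(n_enz), function(i) {
    w <- stats::runif(6, 0, 1)
    w[sample(6, sample(0:2, 1))] <- 0 # some terminal-prone weight patterns
    if (!any(w > 0)) w[sample(6, 1)] <- stats::runif(1, 0.2, 1)
    enzyme_model(paste0("rnd", i), w, k = stats::runif(1, 0.1, 2))
  })
  community_model(
    enzymes = enzymes,
    mix = stats::runif(n_enz, 0.2, 2),
    sorption_rate = sample(c(0, stats::runif(1, 0, 1)), 1),
    pi_uptake_rate = sample(c(0, stats::runif(1, 0, 2)), 1),
    t_lag = sample(c(0, stats::runif(1, 0.5, 1.5)), 1)
  )
}

# phosphate-weighted totals for conservation checks
conservation_residuals <- function(tc) {
  ab <- tc$abundance
  keys <- tc$keys
  sp_cols <- paste0("sp", ifelse(keys == "", "0", keys))
  levels <- nchar(keys)
  sp <- as.matrix(ab[, sp_cols])
  inositol <- rowSums(sp) + ab$sorbed_pool
  phosphate <- as.numeric(sp %*% levels) + 6 * ab$sorbed_pool +
    ab$pi_pool + ab$pi_removed
  list(
    inositol = max(abs(inositol - inositol[1])) / inositol[1],
    phosphate = max(abs(phosphate - phosphate[1])) / phosphate[1]
  )
}
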