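# ---- enzyme and community models ---------------------------------------------

#' Position-preference enzyme model
#'
#' A phytase (or generic inositol-phosphate phosphatase) is modelled by a
#' non-negative preference weight per ring position and an overall first-order
#' rate constant. The rate of removing phosphate from position p of species S
#' is k * w\[p\] (memoryless: the preference depends on the position only, not
#' on the current species). Only weight ratios matter for pathway branching;
#' k sets the time scale.
#'
#' @param name Enzyme name.
#' @param weights Numeric length 6, non-negative position preferences
#'   (positions 1..6); at least one must be positive.
#' @param k Overall rate constant, per day.
#' @param class_label One of "BPP_3PHYTASE", "HAP_6PHYTASE", "FIVE_PHYTASE",
#'   "MINPP", "GENERIC".
#' @return Object of class `phyt_enzyme`.
#' @export
enzyme_model <- function(name, weights, k,
                         class_label = c("GENERIC", "BPP_3PHYTASE",
                                         "HAP_6PHYTASE", "FIVE_PHYTASE",
                                         "MINPP")) {
  class_label <- match.arg(class_label)
  weights <- as.numeric(weights)
  if (length(weights) != 6 || anyNA(weights) || any(weights < 0)) {
    abort("weights must be 6 non-negative numbers (positions 1..6)")
  }
  if (!any(weights > 0)) abort("at least one position weight must be positive")
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0) {
    abort("k must be a single non-negative rate (per day)")
  }
  structure(
    list(name = name, weights = weights, k = k, class_label = class_label),
    class = "phyt_enzyme"
  )
}

#' @export
print.phyt_enzyme <- function(x, ...) {
  cat("<phyt_enzyme> ", x$name, " (", x$class_label, ")\n", sep = "")
  cat("  k =", x$k, "/day; weights:",
      paste(sprintf("w%d=%.3g", 1:6, x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Community model: an enzyme mixture with sorption, Pi scavenging and lag
#'
#' @param enzymes List of [enzyme_model()] objects (may be empty for
#'   sorption-only communities).
#' @param mix Non-negative mixing weights, one per enzyme.
#' @param sorption_rate First-order loss of InsP6 to an inert sorbed pool,
#'   per day (soil particle binding; applies to InsP6 only).
#' @param pi_uptake_rate First-order removal of free inorganic phosphate,
#'   per day (microbial Pi scavenging).
#' @param t_lag Midpoint of the logistic activation of all enzyme rates,
#'   days; 0 disables the lag (activation = 1 throughout).
#' @param tau Logistic steepness of the lag, days.
#' @return Object of class `phyt_community`.
#' @export
community_model <- function(enzymes = list(), mix = rep(1, length(enzymes)),
                            sorption_rate = 0, pi_uptake_rate = 0,
                            t_lag = 0, tau = 0.25) {
  if (inherits(enzymes, "phyt_enzyme")) enzymes <- list(enzymes)
  stopifnot(all(map_lgl(enzymes, inherits, "phyt_enzyme")))
  mix <- as.numeric(mix)
  if (length(mix) != length(enzymes) || any(mix < 0)) {
    abort("mix must be non-negative, one weight per enzyme")
  }
  if (length(enzymes) && !any(mix > 0)) {
    abort("at least one mixing weight must be positive")
  }
  if (sorption_rate < 0 || pi_uptake_rate < 0 || tau <= 0) {
    abort("rates must be non-negative and tau positive")
  }
  structure(
    list(enzymes = enzymes, mix = mix, sorption_rate = sorption_rate,
         pi_uptake_rate = pi_uptake_rate, t_lag = t_lag, tau = tau),
    class = "phyt_community"
  )
}

#' @export
print.phyt_community <- function(x, ...) {
  cat("<phyt_community> ", length(x$enzymes), " enzyme(s)\n", sep = "")
  for (i in seq_along(x$enzymes)) {
    cat(sprintf("  %-20s mix=%.3g k=%.3g (%s)\n", x$enzymes[[i]]$name,
                x$mix[i], x$enzymes[[i]]$k, x$enzymes[[i]]$class_label))
  }
  cat(sprintf("  sorption=%.3g/d, pi_uptake=%.3g/d, t_lag=%.3g d (tau=%.3g)\n",
              x$sorption_rate, x$pi_uptake_rate, x$t_lag, x$tau))
  invisible(x)
}

# logistic activation of enzyme rates (1 everywhere when t_lag <= 0)
activation_factor <- function(community, t) {
  if (community$t_lag <= 0) return(rep(1, length(t)))
  stats::plogis((t - community$t_lag) / community$tau)
}

# ---- master-equation rate matrices -------------------------------------------

# effective per-position removal rate summed over the mixture
community_position_rates <- function(community) {
  rates <- numeric(6)
  for (i in seq_along(community$enzymes)) {
    e <- community$enzymes[[i]]
    rates <- rates + community$mix[i] * e$k * e$weights
  }
  rates
}

#' Build the 64 x 64 master-equation rate matrix
#'
#' Linear kinetics over the degradation DAG: entry (S \ p, S) is the
#' activation-scaled mixture rate of removing position p from S; diagonals
#' carry minus the total out-rate, plus the sorption loss on InsP6.
#' States are ordered as in [species_table()].
#'
#' @param community A [community_model()].
#' @param t Time (days) at which to evaluate the lag activation.
#' @return Dense 64 x 64 matrix, dimnames = species keys.
#' @export
build_rate_matrix <- function(community, t = 0) {
  keys <- all_species_keys()
  n <- length(keys)
  pos_rates <- community_position_rates(community) * activation_factor(community, t)
  Q <- matrix(0, n, n, dimnames = list(keys, keys))
  for (j in seq_len(n)) {
    s <- as_species(keys[j])
    if (!length(s)) next
    for (p in s) {
      ic <- match(paste(setdiff(s, p), collapse = ""), keys)
      Q[ic, j] <- Q[ic, j] + pos_rates[p]
      Q[j, j] <- Q[j, j] - pos_rates[p]
    }
  }
  i6 <- match("123456", keys)
  Q[i6, i6] <- Q[i6, i6] - community$sorption_rate
  Q
}

# Augmented generator split into enzyme-scaled and static parts.
# State layout: 64 species | pi | sorbed | pi_removed | (64 cumulative inflows).
augmented_generators <- function(community, track_flux = FALSE) {
  keys <- all_species_keys()
  n <- length(keys)
  ntot <- n + 3L + if (track_flux) n else 0L
  i_pi <- n + 1L
  i_sorb <- n + 2L
  i_rem <- n + 3L
  Ae <- matrix(0, ntot, ntot) # scaled by activation(t)
  As <- matrix(0, ntot, ntot) # sorption + Pi uptake, time-constant
  pos_rates <- community_position_rates(community)
  for (j in seq_len(n)) {
    s <- as_species(keys[j])
    if (!length(s)) next
    for (p in s) {
      r <- pos_rates[p]
      if (r == 0) next
      ic <- match(paste(setdiff(s, p), collapse = ""), keys)
      Ae[ic, j] <- Ae[ic, j] + r
      Ae[j, j] <- Ae[j, j] - r
      Ae[i_pi, j] <- Ae[i_pi, j] + r # one Pi per removal
      if (track_flux) Ae[n + 3L + ic, j] <- Ae[n + 3L + ic, j] + r
    }
  }
  i6 <- match("123456", keys)
  As[i6, i6] <- As[i6, i6] - community$sorption_rate
  As[i_sorb, i6] <- community$sorption_rate
  As[i_pi, i_pi] <- -community$pi_uptake_rate
  As[i_rem, i_pi] <- community$pi_uptake_rate
  list(Ae = Ae, As = As, n = n, keys = keys,
       i_pi = i_pi, i_sorb = i_sorb, i_rem = i_rem, track_flux = track_flux)
}

species_col_names <- function(keys) paste0("sp", ifelse(keys == "", "0", keys))

#' Simulate a phytate degradation time course
#'
#' Integrates the linear master equation for a community acting on an initial
#' species abundance vector, with bookkeeping of released inorganic phosphate
#' (one Pi per removal event), Pi scavenging, and sorbed InsP6.
#'
#' @param community A [community_model()].
#' @param x0 Initial abundances: named numeric vector over species keys
#'   (missing species are 0), e.g. `c("123456" = 0.95, "23456" = 0.05)`, or a
#'   class-profile tibble (see [profile_to_species()]).
#' @param times Strictly increasing time grid starting at 0, days.
#' @param pi0 Initial free inorganic phosphate.
#' @param method "expm" (matrix exponential, exact for the time-homogeneous
#'   case), "rk4" (fixed-step 4th-order, required when a lag makes rates
#'   time-dependent) or "auto" (default: expm without lag, rk4 with).
#' @param step RK4 step, days (default 0.001).
#' @param track_flux Also accumulate the cumulative inflow into every species
#'   (total throughput), for comparison with [pathway_flux()].
#' @return Object of class `phyt_timecourse`: list with `abundance` (wide
#'   tibble: `time`, one `sp<key>` column per species, `pi_pool`,
#'   `sorbed_pool`, `pi_removed`), `keys`, `community`, and optionally
#'   `cumulative_inflow` (tibble `key`, `inflow`) at the final time.
#' @export
simulate_timecourse <- function(community, x0, times, pi0 = 0,
                                method = c("auto", "expm", "rk4"),
                                step = 0.001, track_flux = FALSE) {
  method <- match.arg(method)
  times <- as.numeric(times)
  if (length(times) < 1 || times[1] != 0 || any(diff(times) <= 0)) {
    abort("times must be strictly increasing and start at 0")
  }
  gen <- augmented_generators(community, track_flux = track_flux)
  keys <- gen$keys
  x_species <- numeric(gen$n)
  names(x_species) <- keys
  pi_extra <- 0
  if (is.data.frame(x0)) {
    x0 <- profile_to_species(x0)
    pi_extra <- attr(x0, "pi") %||% 0
  }
  if (length(x0) && is.null(names(x0))) {
    abort("x0 must be a named vector of species keys")
  }
  nm <- ifelse(names(x0) == "Ins", "", names(x0))
  pos <- match(nm, keys)
  if (anyNA(pos)) {
    abort(paste("unknown species keys in x0:",
                paste(names(x0)[is.na(pos)], collapse = ", ")))
  }
  if (any(x0 < 0)) abort("x0 must be non-negative")
  for (i in seq_along(pos)) x_species[pos[i]] <- x_species[pos[i]] + x0[i]
  ntot <- nrow(gen$Ae)
  x <- numeric(ntot)
  x[seq_len(gen$n)] <- x_species
  x[gen$i_pi] <- pi0 + pi_extra

  has_lag <- community$t_lag > 0
  if (method == "auto") method <- if (has_lag) "rk4" else "expm"
  if (method == "expm" && has_lag) {
    abort("expm method requires time-constant rates; use rk4 for lagged communities")
  }

  out <- matrix(0, length(times), ntot)
  out[1, ] <- x
  if (length(times) > 1) {
    if (method == "expm") {
      A <- gen$Ae + gen$As
      dts <- diff(times)
      # cache propagators for repeated identical intervals
      prop_cache <- list()
      for (i in seq_along(dts)) {
        keyd <- format(dts[i], digits = 15)
        if (is.null(prop_cache[[keyd]])) {
          prop_cache[[keyd]] <- as.matrix(Matrix::expm(A * dts[i]))
        }
        x <- prop_cache[[keyd]] %*% x
        out[i + 1, ] <- x
      }
    } else {
      f <- function(t, x) {
        a <- activation_factor(community, t)
        a * (gen$Ae %*% x) + gen$As %*% x
      }
      for (i in seq_along(diff(times))) {
        t0 <- times[i]; t1 <- times[i + 1]
        nstep <- max(1L, ceiling((t1 - t0) / step))
        h <- (t1 - t0) / nstep
        tt <- t0
        for (s in seq_len(nstep)) {
          k1 <- f(tt, x)
          k2 <- f(tt + h / 2, x + h / 2 * k1)
          k3 <- f(tt + h / 2, x + h / 2 * k2)
          k4 <- f(tt + h, x + h * k3)
          x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
          tt <- tt + h
        }
        out[i + 1, ] <- x
      }
    }
  }

  ab <- as_tibble(out[, seq_len(gen$n), drop = FALSE],
                  .name_repair = ~species_col_names(keys))
  ab <- mutate(ab,
    time = times,
    pi_pool = out[, gen$i_pi],
    sorbed_pool = out[, gen$i_sorb],
    pi_removed = out[, gen$i_rem],
    .before = 1
  )
  res <- list(abundance = ab, keys = keys, community = community)
  if (track_flux) {
    res$cumulative_inflow <- tibble(
      key = keys,
      inflow = out[nrow(out), gen$n + 3L + seq_len(gen$n)]
    )
  }
  structure(res, class = "phyt_timecourse")
}

#' @export
print.phyt_timecourse <- function(x, ...) {
  tmax <- max(x$abundance$time)
  cat("<phyt_timecourse> ", nrow(x$abundance), " time points over ",
      tmax, " days\n", sep = "")
  i6 <- x$abundance[["sp123456"]]
  cat(sprintf("  InsP6: %.4g -> %.4g; Pi pool at end: %.4g\n",
              i6[1], i6[length(i6)],
              x$abundance$pi_pool[nrow(x$abundance)]))
  invisible(x)
}

#' Convert a class profile to species abundances
#'
#' Distributes each chromatographic class amount equally over the member
#' species of the class (enantiomers are indistinguishable so the even split
#' is the maximum-entropy choice; lumped level classes split over all species
#' of the level). The pooled "Pi/InsP1" class is split between the Pi pool
#' (returned separately as the "Pi" attribute) and nothing else: pooled
#' amounts are treated as inorganic phosphate.
#'
#' @param profile Tibble with columns `class` and one of `amount` /
#'   `mole_fraction`.
#' @return Named numeric vector over species keys; attribute `pi` carries the
#'   pooled Pi amount.
#' @export
profile_to_species <- function(profile) {
  stopifnot(is.data.frame(profile), "class" %in% names(profile))
  val_col <- if ("amount" %in% names(profile)) "amount" else "mole_fraction"
  classes <- chrom_class_table()
  x <- numeric(0)
  pi_amt <- 0
  for (i in seq_len(nrow(profile))) {
    cl <- profile$class[i]
    amt <- profile[[val_col]][i]
    if (cl %in% c("Pi/InsP1", "Pi")) { pi_amt <- pi_amt + amt; next }
    row <- classes[classes$canonical_name == cl, ]
    if (nrow(row) == 0) abort(paste("unknown chromatographic class:", cl))
    members <- row$members[[1]]
    share <- amt / length(members)
    for (m in members) x[m] <- (if (m %in% names(x)) x[m] else 0) + share
  }
  attr(x, "pi") <- pi_amt
  x
}

# ---- pathway flux ------------------------------------------------------------

#' Pathway-flux distribution of an enzyme
#'
#' Probability that a degrading molecule passes through each phosphorylation
#' state, for a single position-preference enzyme: flux starts at 1 on InsP6
#' and splits at each species proportionally to the positive weights of its
#' remaining phosphorylated positions (dynamic programming down the
#' degradation DAG). Species where all remaining positions have zero weight
#' are terminal: their flux is retained, not passed on.
#'
#' @param enzyme An [enzyme_model()].
#' @return Tibble: `key`, `level`, `flux`, `class` (lumped class name).
#' @export
pathway_flux <- function(enzyme) {
  stopifnot(inherits(enzyme, "phyt_enzyme"))
  if (!any(enzyme$weights > 0)) abort("all-zero weights")
  tab <- species_table()
  keys <- tab$key
  flux <- numeric(length(keys))
  flux[match("123456", keys)] <- 1
  for (lev in 6:1) {
    for (i in which(tab$level == lev)) {
      f <- flux[i]
      if (f == 0) next
      s <- as_species(keys[i])
      w <- enzyme$weights[s]
      tot <- sum(w)
      if (tot <= 0) next # terminal species
      for (j in seq_along(s)) {
        if (w[j] == 0) next
        ic <- match(paste(setdiff(s, s[j]), collapse = ""), keys)
        flux[ic] <- flux[ic] + f * w[j] / tot
      }
    }
  }
  tibble(
    key = keys,
    level = tab$level,
    flux = flux,
    class = species_class_map(lumping = TRUE)
  )
}

#' Aggregate pathway flux to chromatographic classes
#'
#' @param enzyme An [enzyme_model()].
#' @param lumping Collapse levels <= 3 (default TRUE).
#' @return Tibble `class`, `level`, `flux`, summed over class members.
#' @export
class_flux <- function(enzyme, lumping = TRUE) {
  fl <- pathway_flux(enzyme)
  if (!lumping) {
    fl$class <- species_class_map(lumping = FALSE)
  }
  fl %>%
    group_by(.data$class, .data$level) %>%
    summarise(flux = sum(.data$flux), .groups = "drop") %>%
    arrange(dplyr::desc(.data$level), .data$class)
}

# ---- class profiles ----------------------------------------------------------

# the lumped chromatographic class universe, with member species keys
chrom_class_table <- function() {
  cls <- enumerate_classes(lumping = TRUE)
  # pooled Pi/InsP1 class replaces InsP1; free inositol is invisible to the
  # detector and is excluded from chromatographic profiles
  insp1 <- cls[cls$canonical_name == "InsP1", ]
  pooled <- tibble(
    level = 1L, canonical_name = "Pi/InsP1",
    members = insp1$members, is_meso = FALSE, lumped = TRUE
  )
  cls %>%
    filter(!.data$canonical_name %in% c("Ins", "InsP1")) %>%
    bind_rows(pooled) %>%
    arrange(dplyr::desc(.data$level))
}

#' The chromatographic class universe
#'
#' Canonical names of the 17 classes visible to the HPLC method with default
#' lumping: InsP6, four InsP5 classes, nine InsP4 classes, InsP3, InsP2 and
#' the pooled Pi/InsP1 class (inorganic phosphate co-elutes with InsP1).
#'
#' @return Character vector of class names in canonical (level-descending)
#'   order.
#' @export
chrom_class_universe <- function() chrom_class_table()$canonical_name

#' Class profile at one time point of a time course
#'
#' Sums species abundances within each chromatographic class (linear
#' interpolation between grid points) and appends the pooled Pi/InsP1 class.
#' Sorbed material is inert and excluded.
#'
#' @param tc A [simulate_timecourse()] result.
#' @param t Time, days.
#' @param include_pi Include the Pi pool in the mole-fraction normalization
#'   (default TRUE).
#' @return Tibble: `class`, `amount`, `mole_fraction`.
#' @export
class_profile <- function(tc, t, include_pi = TRUE) {
  stopifnot(inherits(tc, "phyt_timecourse"))
  ab <- tc$abundance
  if (t < min(ab$time) || t > max(ab$time)) abort("t outside simulated range")
  row <- map_dbl(names(ab), function(cn) stats::approx(ab$time, ab[[cn]], xout = t)$y)
  names(row) <- names(ab)
  ctab <- chrom_class_table()
  cols <- species_col_names(tc$keys)
  amounts <- map_dbl(seq_len(nrow(ctab)), function(i) {
    sum(row[cols[match(ctab$members[[i]], tc$keys)]])
  })
  amounts[ctab$canonical_name == "Pi/InsP1"] <-
    amounts[ctab$canonical_name == "Pi/InsP1"] + row[["pi_pool"]]
  prof <- tibble(class = ctab$canonical_name, amount = amounts)
  denom_set <- if (include_pi) prof$amount else
    prof$amount[prof$class != "Pi/InsP1"]
  denom <- sum(denom_set)
  prof$mole_fraction <- if (denom > 0) prof$amount / denom else 0 * prof$amount
  prof
}

#' Read / write a class profile as TSV
#'
#' Columns `class` and `mole_fraction` (plus `amount` when present).
#'
#' @param profile Profile tibble.
#' @param path File path.
#' @return `read_class_profile`: the profile tibble;
#'   `write_class_profile`: the path, invisibly.
#' @export
write_class_profile <- function(profile, path) {
  cols <- intersect(c("class", "amount", "mole_fraction"), names(profile))
  readr::write_tsv(profile[cols], path)
  invisible(path)
}

#' @rdname write_class_profile
#' @export
read_class_profile <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Export a time course as TSV
#'
#' One row per time point; columns `time`, one per species key (canonical
#' `sp<key>` naming, `sp0` = free inositol), `pi_pool`, `sorbed_pool`,
#' `pi_removed`.
#'
#' @param tc A [simulate_timecourse()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  readr::write_tsv(tc$abundance, path)
  invisible(path)
}
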