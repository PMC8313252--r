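# ---- retention table ----------------------------------------------------------

#' Default retention table for the inositol-phosphate gradient
#'
#' Retention times (min) per chromatographic class. Three anchors are
#' literature values for this column/gradient family: the pooled Pi/InsP1
#' class at the solvent front (2.8 min), InsP5 \[1/3-OH\] at 28 min and InsP6
#' at 37 min. All other entries are invented defaults, monotone with
#' phosphate number, with the seven InsP4 standards in their ladder order.
#' The two InsP4 classes absent from the standards ladder
#' (Ins(1,2,3,5)P4, Ins(1,3,4,6)P4) have no default entry; set
#' `include_extra_insp4 = TRUE` to add configurable slots for them.
#'
#' @param sigma Gaussian peak width (standard deviation), min.
#' @param include_extra_insp4 Add invented slots for the two InsP4 classes
#'   missing from the standards ladder.
#' @return Tibble: `class`, `rt_min`, `sigma_min`, `anchored`
#'   ("paper" for the three anchored entries, otherwise "invented").
#' @export
retention_table <- function(sigma = 0.25, include_extra_insp4 = FALSE) {
  rt <- tibble::tribble(
    ~class,                 ~rt_min, ~anchored,
    "Pi/InsP1",                 2.8, "paper",
    "InsP2",                    8.0, "invented",
    "InsP3",                   14.0, "invented",
    "d/l-Ins(1,4,5,6)P4",      18.0, "invented",
    "Ins(2,4,5,6)P4",          19.0, "invented",
    "d/l-Ins(1,2,5,6)P4",      20.0, "invented",
    "d/l-Ins(1,3,4,5)P4",      21.0, "invented",
    "d/l-Ins(1,2,4,5)P4",      22.0, "invented",
    "d/l-Ins(1,2,3,4)P4",      23.0, "invented",
    "d/l-Ins(1,2,4,6)P4",      24.0, "invented",
    "InsP5 [2-OH]",            27.0, "invented",
    "InsP5 [1/3-OH]",          28.0, "paper",
    "InsP5 [4/6-OH]",          29.5, "invented",
    "InsP5 [5-OH]",            31.0, "invented",
    "InsP6",                   37.0, "paper"
  )
  if (include_extra_insp4) {
    rt <- bind_rows(rt, tibble(
      class = c("Ins(1,2,3,5)P4", "Ins(1,3,4,6)P4"),
      rt_min = c(25.0, 26.0),
      anchored = "invented"
    ))
  }
  rt %>%
    mutate(sigma_min = sigma, .after = "rt_min") %>%
    arrange(.data$rt_min)
}

#' Write / read a retention table as TSV
#'
#' @param rt Retention-table tibble.
#' @param path File path.
#' @return The path (write) or the tibble (read).
#' @export
write_retention_table <- function(rt, path) {
  readr::write_tsv(rt, path)
  invisible(path)
}

#' @rdname write_retention_table
#' @export
read_retention_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

# per-class molar response factor
response_factors <- function(classes, response = c("equal", "per_phosphate")) {
  response <- match.arg(response)
  if (response == "equal") return(rep(1, length(classes)))
  lev <- chrom_class_table()
  levmap <- stats::setNames(lev$level, lev$canonical_name)
  levmap[["Pi/InsP1"]] <- 1L
  unname(levmap[classes])
}

# ---- synthesis -----------------------------------------------------------------

#' Synthesize a detector trace from a class profile
#'
#' Forward model of the HPLC trace: each class contributes a Gaussian of unit
#' area scaled by amount x response factor at its retention time, on a flat
#' baseline with optional seeded white noise.
#'
#' @param profile Tibble with columns `class` and `amount` (or
#'   `mole_fraction`, used as amount).
#' @param rt Retention table ([retention_table()]).
#' @param times Sampling grid, min (uniform).
#' @param baseline Constant baseline level.
#' @param noise_sd Gaussian noise standard deviation (0 = noise-free).
#' @param seed Seed for the noise; required for reproducibility when
#'   `noise_sd > 0`.
#' @param response "equal" molar response (default) or "per_phosphate".
#' @return Chromatogram tibble: `time_min`, `signal`.
#' @export
synthesize_chromatogram <- function(profile, rt = retention_table(),
                                    times = seq(0, 40, by = 0.01),
                                    baseline = 0, noise_sd = 0, seed = NULL,
                                    response = c("equal", "per_phosphate")) {
  response <- match.arg(response)
  val_col <- if ("amount" %in% names(profile)) "amount" else "mole_fraction"
  active <- profile[profile[[val_col]] > 0, ]
  missing_cls <- setdiff(active$class, rt$class)
  if (length(missing_cls)) {
    abort(paste("classes missing from the retention table:",
                paste(missing_cls, collapse = ", ")))
  }
  signal <- rep(baseline, length(times))
  if (nrow(active)) {
    resp <- response_factors(active$class, response)
    for (i in seq_len(nrow(active))) {
      entry <- rt[rt$class == active$class[i], ]
      signal <- signal + active[[val_col]][i] * resp[i] *
        stats::dnorm(times, mean = entry$rt_min[1], sd = entry$sigma_min[1])
    }
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(times), 0, noise_sd) else
      withr::with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
    signal <- signal + noise
  }
  tibble(time_min = as.numeric(times), signal = signal)
}

# ---- peak detection ------------------------------------------------------------

#' Detect peaks in a chromatogram
#'
#' Local maxima of the moving-average-smoothed trace above baseline plus a
#' signal-to-noise threshold, with a prominence floor relative to the tallest
#' peak; apex refined by parabolic interpolation; peaks closer than the merge
#' distance are merged keeping the taller apex.
#'
#' @param chrom Chromatogram tibble (`time_min`, `signal`).
#' @param smooth_window Moving-average window, points (odd; default 5).
#' @param min_snr Minimum height above baseline in noise-sd units (default 5).
#' @param min_prominence_frac Minimum height as a fraction of the tallest
#'   peak's height (default 0.005).
#' @param merge_distance Peaks closer than this (min) are merged (default 0.3).
#' @return Peak tibble: `apex_time`, `height` (above baseline), `index`;
#'   attributes `baseline` and `noise_sd` (estimates).
#' @export
detect_peaks <- function(chrom, smooth_window = 5, min_snr = 5,
                         min_prominence_frac = 0.005, merge_distance = 0.3) {
  stopifnot(all(c("time_min", "signal") %in% names(chrom)))
  n <- nrow(chrom)
  if (n < smooth_window) abort("trace shorter than the smoothing window")
  w <- as.integer(smooth_window)
  if (w %% 2L == 0L) w <- w + 1L
  s <- as.numeric(stats::filter(chrom$signal, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- chrom$signal[is.na(s)]
  baseline <- stats::median(s)
  noise_sd <- stats::mad(diff(chrom$signal)) / sqrt(2)
  smax <- max(s)
  thr <- max(min_snr * noise_sd, min_prominence_frac * (smax - baseline), 1e-12)

  idx <- which(s[c(-1, -n)] > s[seq_len(n - 2)] & s[c(-1, -n)] >= s[-(1:2)]) + 1L
  idx <- idx[s[idx] - baseline >= thr]
  # topographic prominence: height above the higher of the two saddles
  # towards the nearest taller terrain; kills noise bumps on peak tails
  prominence <- vapply(idx, function(i) {
    left <- s[seq_len(i - 1)]
    higher_l <- which(left > s[i])
    min_l <- if (length(higher_l)) min(s[(max(higher_l) + 1):(i - 1)]) else baseline
    right <- s[(i + 1):n]
    higher_r <- which(right > s[i])
    min_r <- if (length(higher_r)) min(s[(i + 1):(i + min(higher_r) - 1)]) else baseline
    s[i] - max(min_l, min_r)
  }, 0)
  idx <- idx[prominence >= thr]
  if (!length(idx)) {
    out <- tibble(apex_time = numeric(0), height = numeric(0), index = integer(0))
    attr(out, "baseline") <- baseline
    attr(out, "noise_sd") <- noise_sd
    return(out)
  }
  dt <- chrom$time_min[2] - chrom$time_min[1]
  apex <- map_dbl(idx, function(i) {
    y0 <- s[i - 1]; y1 <- s[i]; y2 <- s[i + 1]
    denom <- y0 - 2 * y1 + y2
    offset <- if (denom != 0) 0.5 * (y0 - y2) / denom else 0
    chrom$time_min[i] + offset * dt
  })
  pk <- tibble(apex_time = apex, height = s[idx] - baseline, index = idx) %>%
    arrange(.data$apex_time)
  # merge close peaks, keep the taller
  repeat {
    if (nrow(pk) < 2) break
    gaps <- diff(pk$apex_time)
    j <- which(gaps < merge_distance)
    if (!length(j)) break
    j <- j[1]
    drop <- if (pk$height[j] >= pk$height[j + 1]) j + 1 else j
    pk <- pk[-drop, ]
  }
  attr(pk, "baseline") <- baseline
  attr(pk, "noise_sd") <- noise_sd
  pk
}

# ---- integration and assignment ------------------------------------------------

#' Integrate detected peaks and assign them to classes
#'
#' Each peak is assigned to the nearest retention-table entry within the
#' tolerance (ties by distance; at most one peak per class — when several
#' peaks fall on one class the tallest keeps it). Areas are trapezoidal over
#' apex +/- 3 sigma of the assigned class, bounded by the valleys towards
#' neighbouring peaks, above the detection baseline.
#'
#' @param peaks [detect_peaks()] result.
#' @param chrom The chromatogram the peaks came from.
#' @param rt Retention table.
#' @param tolerance Maximum |apex - retention time| for assignment, min
#'   (default 0.35; must stay below half the smallest inter-class gap).
#' @return Peak tibble with `area` and `class` (NA when unassigned) added.
#' @export
integrate_and_assign <- function(peaks, chrom, rt = retention_table(),
                                 tolerance = 0.35) {
  baseline <- attr(peaks, "baseline") %||% 0
  npk <- nrow(peaks)
  sigma_default <- stats::median(rt$sigma_min)
  cls <- rep(NA_character_, npk)
  sig <- rep(sigma_default, npk)
  for (i in seq_len(npk)) {
    d <- abs(rt$rt_min - peaks$apex_time[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tolerance) {
      cls[i] <- rt$class[j]
      sig[i] <- rt$sigma_min[j]
    }
  }
  # enforce at most one peak per class: tallest wins
  for (cl in unique(stats::na.omit(cls))) {
    hit <- which(cls == cl)
    if (length(hit) > 1) cls[hit[hit != hit[which.max(peaks$height[hit])]]] <- NA
  }
  t <- chrom$time_min
  y <- chrom$signal - baseline
  area <- map_dbl(seq_len(npk), function(i) {
    lo <- peaks$apex_time[i] - 3 * sig[i]
    hi <- peaks$apex_time[i] + 3 * sig[i]
    # bound by valley towards neighbouring peaks
    if (i > 1) {
      seg <- which(t >= peaks$apex_time[i - 1] & t <= peaks$apex_time[i])
      if (length(seg)) lo <- max(lo, t[seg[which.min(y[seg])]])
    }
    if (i < npk) {
      seg <- which(t >= peaks$apex_time[i] & t <= peaks$apex_time[i + 1])
      if (length(seg)) hi <- min(hi, t[seg[which.min(y[seg])]])
    }
    win <- which(t >= lo & t <= hi)
    if (length(win) < 2) return(0)
    sum(diff(t[win]) * (utils::head(y[win], -1) + utils::tail(y[win], -1)) / 2)
  })
  out <- peaks %>% mutate(area = pmax(area, 0), class = cls)
  attr(out, "baseline") <- baseline
  attr(out, "noise_sd") <- attr(peaks, "noise_sd")
  out
}

#' Quantify assigned peaks into a class profile
#'
#' Converts peak areas to mole amounts via the response model and normalizes
#' to mole fractions over the chromatographic class universe. Unassigned
#' peaks are reported in the `unassigned` attribute (and a warning), never
#' silently dropped.
#'
#' @param peaks Assigned peak tibble from [integrate_and_assign()].
#' @param response "equal" molar response (default) or "per_phosphate".
#' @param include_pi Include the pooled Pi/InsP1 class in the normalization
#'   (default TRUE).
#' @return Profile tibble over [chrom_class_universe()]: `class`, `amount`,
#'   `mole_fraction` (classes without a peak have 0).
#' @export
quantify <- function(peaks, response = c("equal", "per_phosphate"),
                     include_pi = TRUE) {
  response <- match.arg(response)
  stopifnot("area" %in% names(peaks))
  unassigned <- peaks %>% filter(is.na(.data$class))
  assigned <- peaks %>% filter(!is.na(.data$class))
  if (nrow(unassigned)) {
    warning(sprintf("%d unassigned peak(s) at %s min excluded from the profile",
                    nrow(unassigned),
                    paste(sprintf("%.2f", unassigned$apex_time), collapse = ", ")))
  }
  universe <- chrom_class_universe()
  amount <- stats::setNames(numeric(length(universe)), universe)
  if (nrow(assigned)) {
    resp <- response_factors(assigned$class, response)
    amount[assigned$class] <- assigned$area / resp
  }
  prof <- tibble(class = universe, amount = unname(amount))
  denom <- if (include_pi) sum(prof$amount) else
    sum(prof$amount[prof$class != "Pi/InsP1"])
  prof$mole_fraction <- if (denom > 0) prof$amount / denom else 0 * prof$amount
  attr(prof, "unassigned") <- unassigned
  prof
}

# ---- chromatogram I/O -----------------------------------------------------------

#' Read / write chromatogram CSV
#'
#' CSV dialect: header `time_min,signal`, decimal point, UTF-8. The grid must
#' be uniform; write -> read round-trips losslessly to 1e-9.
#'
#' @param path File path.
#' @param chrom Chromatogram tibble (`time_min`, `signal`).
#' @return `read_chromatogram`: the chromatogram tibble. `write_chromatogram`:
#'   the path, invisibly.
#' @export
read_chromatogram <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || trimws(lines[1]) != "time_min,signal") {
    abort("malformed chromatogram CSV: expected header 'time_min,signal'")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    abort(sprintf("parse error at line %d: expected 2 comma-separated fields", bad + 1L))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    abort(sprintf("parse error at line %d: non-numeric value", bad + 1L))
  }
  times <- m[, 1]
  if (length(times) > 2) {
    dts <- diff(times)
    rel <- abs(dts - dts[1]) / max(abs(dts[1]), 1e-12)
    if (any(rel > 1e-6)) {
      bad <- which(rel > 1e-6)[1]
      abort(sprintf(
        "non-uniform time grid: interval %d (%.9g to %.9g min) differs from the first interval (%.9g min)",
        bad, times[bad], times[bad + 1], dts[1]))
    }
  }
  tibble(time_min = times, signal = m[, 2])
}

#' @rdname read_chromatogram
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(all(c("time_min", "signal") %in% names(chrom)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_min,signal", con)
  writeLines(sprintf("%.12g,%.12g", chrom$time_min, chrom$signal), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
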