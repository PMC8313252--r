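# ---- substrate QC --------------------------------------------------------------

#' Substrate purity check
#'
#' Commercial phytate is impure; the screen requires knowing how much of the
#' starting material is actually InsP6. Impurity = 1 - InsP6 mole fraction.
#'
#' @param profile Normalized class profile (`class`, `mole_fraction` summing
#'   to 1 within 1e-6).
#' @param impurity_threshold Maximum tolerated impurity fraction
#'   (default 0.10).
#' @return Tibble with one row: `impurity`, `pass`, plus attribute
#'   `impurity_classes` listing every non-InsP6 class present.
#' @export
substrate_qc <- function(profile, impurity_threshold = 0.10) {
  stopifnot(all(c("class", "mole_fraction") %in% names(profile)))
  tot <- sum(profile$mole_fraction)
  if (abs(tot - 1) > 1e-6) {
    abort(sprintf("profile is not normalized (mole fractions sum to %.6g)", tot))
  }
  insp6 <- sum(profile$mole_fraction[profile$class == "InsP6"])
  impurity <- 1 - insp6
  listed <- profile %>%
    filter(.data$class != "InsP6", .data$mole_fraction > 0) %>%
    arrange(dplyr::desc(.data$mole_fraction))
  out <- tibble(impurity = impurity, pass = impurity <= impurity_threshold)
  attr(out, "impurity_classes") <- listed
  out
}

#' Difference between two class profiles
#'
#' Per-class change test - reference, on normalized mole fractions (mole
#' fractions absorb extraction-efficiency differences between e.g. cleared
#' and non-cleared agar zones). Flags classes appearing above the reporting
#' threshold in the test profile but not in the reference.
#'
#' @param test,reference Normalized profiles over the same class universe.
#' @param theta_report Detection threshold for "an intermediate is
#'   identified": mole fraction 0.01 by default.
#' @return Tibble: `class`, `test`, `reference`, `delta`, `appeared`.
#' @export
diff_profiles <- function(test, reference, theta_report = 0.01) {
  if (!setequal(test$class, reference$class)) {
    only_t <- setdiff(test$class, reference$class)
    only_r <- setdiff(reference$class, test$class)
    abort(paste0(
      "class universes differ; only in test: {",
      paste(only_t, collapse = ", "), "}; only in reference: {",
      paste(only_r, collapse = ", "), "}"))
  }
  ref <- reference %>% select("class", reference = "mole_fraction")
  test %>%
    select("class", test = "mole_fraction") %>%
    left_join(ref, by = "class") %>%
    mutate(
      delta = .data$test - .data$reference,
      appeared = .data$test >= theta_report & .data$reference < theta_report
    )
}

#' Remaining InsP6 fraction between two time points
#'
#' @param t_n,t_0 Profiles at the later and the initial time point, carrying
#'   `amount` on a shared basis (or comparable `mole_fraction`).
#' @return Remaining fraction of the starting InsP6, clipped to \[0, 1\].
#' @export
degradation_extent <- function(t_n, t_0) {
  val_col <- if ("amount" %in% names(t_0) && any(t_0$amount > 0)) "amount" else "mole_fraction"
  f0 <- sum(t_0[[val_col]][t_0$class == "InsP6"])
  fn <- sum(t_n[[val_col]][t_n$class == "InsP6"])
  if (f0 <= 0) abort("no InsP6 in the starting profile")
  min(max(fn / f0, 0), 1)
}

# ---- phytase-class inference -----------------------------------------------------

#' Default classifier thresholds
#'
#' @return Named list: `activity_threshold` (minimum InsP6 loss fraction to
#'   call activity, 0.05), `dominance_share` (0.5), `dominance_ratio` (2,
#'   over the runner-up), `minpp_gate` (0.05 InsP5-share bounds for the 5-OH
#'   presence / 1/3-OH absence gates), `theta_report` (0.01 mole fraction).
#' @export
classifier_params <- function() {
  list(
    activity_threshold = 0.05,
    dominance_share = 0.5,
    dominance_ratio = 2,
    minpp_gate = 0.05,
    theta_report = 0.01
  )
}

#' Infer the phytase class from isomer profiles
#'
#' Rule cascade over the InsP5 isomer pattern, mirroring how a
#' chromatographer reads the traces: (1) no appreciable InsP6 loss ->
#' NO_ACTIVITY; (2) compute InsP5 class shares among total InsP5 (on the
#' baseline-corrected increase over `t_0`, so substrate impurities do not
#' masquerade as products); a class is dominant if its share is at least
#' `dominance_share` and at least `dominance_ratio` times the runner-up;
#' (3) dominant 1/3-OH -> PHYTASE_3; dominant 4/6-OH with 5-OH below the gate
#' -> PHYTASE_4_6; dominant 5-OH -> PHYTASE_5; dominant 2-OH ->
#' UNCLASSIFIED_2POS; (4) dominant 4/6-OH with 5-OH at or above the gate and
#' 1/3-OH below it -> MINPP_LIKE; (5) otherwise MIXED_COMMUNITY (also when
#' >= 3 InsP5 classes and >= 3 InsP4 classes sit above the reporting
#' threshold; a single promiscuous MINPP produces the same qualitative
#' pattern, so MINPP compatibility is noted in the evidence).
#'
#' @param t_n Profile after incubation (`class`, `mole_fraction`, optionally
#'   `amount`).
#' @param t_0 Starting profile (same universe).
#' @param params Thresholds, see [classifier_params()].
#' @return Object of class `phyt_classification`: list with `label`,
#'   `evidence` (tibble of InsP5 shares and intermediate counts), `notes`.
#' @export
classify_activity <- function(t_n, t_0, params = classifier_params()) {
  insp5_classes <- c("InsP5 [1/3-OH]", "InsP5 [2-OH]", "InsP5 [4/6-OH]", "InsP5 [5-OH]")
  if (!all(insp5_classes %in% t_n$class) || !all(insp5_classes %in% t_0$class)) {
    abort("profiles must cover all four InsP5 classes")
  }
  remaining <- degradation_extent(t_n, t_0)
  loss <- 1 - remaining

  # fractions of total inositol phosphate: the Pi/InsP1 pool is excluded from
  # the denominator, which makes the cascade invariant to Pi-pool
  # inclusion/exclusion and to overall profile scaling
  getf <- function(p, cls) {
    denom <- sum(p$mole_fraction[p$class != "Pi/InsP1"])
    v <- p$mole_fraction[match(cls, p$class)]
    ifelse(is.na(v), 0, v) / max(denom, .Machine$double.eps)
  }
  # baseline-corrected product increase; substrate impurities cancel
  delta5 <- pmax(getf(t_n, insp5_classes) - getf(t_0, insp5_classes), 0)
  tot5 <- sum(delta5)
  shares <- if (tot5 > 0) delta5 / tot5 else rep(0, 4)
  names(shares) <- insp5_classes

  ctab <- chrom_class_table()
  insp4_classes <- ctab$canonical_name[ctab$level == 4]
  insp3_classes <- ctab$canonical_name[ctab$level == 3]
  delta4 <- pmax(getf(t_n, insp4_classes) - getf(t_0, insp4_classes), 0)
  delta3 <- pmax(getf(t_n, insp3_classes) - getf(t_0, insp3_classes), 0)
  n5 <- sum(delta5 >= params$theta_report)
  n4 <- sum(delta4 >= params$theta_report)
  n3 <- sum(delta3 >= params$theta_report)

  ord <- order(shares, decreasing = TRUE)
  top <- shares[ord[1]]
  runner <- shares[ord[2]]
  dominant <- tot5 > 0 && top >= params$dominance_share &&
    top >= params$dominance_ratio * max(runner, .Machine$double.eps)
  dom_class <- if (dominant) names(shares)[ord[1]] else NA_character_

  notes <- character(0)
  label <- NULL
  if (loss < params$activity_threshold) {
    label <- "NO_ACTIVITY"
    notes <- c(notes, sprintf("InsP6 loss %.1f%% below the %.0f%% activity threshold",
                              100 * loss, 100 * params$activity_threshold))
  } else if (dominant) {
    g <- params$minpp_gate
    if (dom_class == "InsP5 [1/3-OH]") {
      label <- "PHYTASE_3"
    } else if (dom_class == "InsP5 [4/6-OH]" && shares[["InsP5 [5-OH]"]] < g) {
      label <- "PHYTASE_4_6"
    } else if (dom_class == "InsP5 [5-OH]") {
      label <- "PHYTASE_5"
    } else if (dom_class == "InsP5 [2-OH]") {
      label <- "UNCLASSIFIED_2POS"
      notes <- c(notes, "initial 2-position attack has no assigned EC phytase class")
    } else if (dom_class == "InsP5 [4/6-OH]" &&
               shares[["InsP5 [5-OH]"]] >= g &&
               shares[["InsP5 [1/3-OH]"]] < g) {
      label <- "MINPP_LIKE"
      notes <- c(notes,
        "dominant 4/6-OH with a smaller 5-OH peak and little 1/3-OH attack")
    }
  }
  if (is.null(label)) {
    label <- "MIXED_COMMUNITY"
    if (n5 >= 3 && n4 >= 3) {
      notes <- c(notes, sprintf(
        "%d InsP5, %d InsP4 and %d InsP3 classes above the reporting threshold",
        n5, n4, n3))
    }
    notes <- c(notes, paste(
      "pattern also compatible with a single promiscuous MINPP enzyme;",
      "multiple InsP5/InsP4/InsP3 intermediates arise either way"))
  }

  evidence <- tibble(
    metric = c("insp6_remaining", "insp6_loss",
               paste0("share_", gsub("[] []", "", insp5_classes)),
               "n_insp5_above_theta", "n_insp4_above_theta", "n_insp3_above_theta"),
    value = c(remaining, loss, unname(shares), n5, n4, n3)
  )
  structure(
    list(label = label, evidence = evidence, shares = shares,
         dominant_class = dom_class, notes = notes, params = params),
    class = "phyt_classification"
  )
}

#' @export
print.phyt_classification <- function(x, ...) {
  cat("<phyt_classification> label:", x$label, "\n")
  sh <- sprintf("  %-16s %.3f", names(x$shares), x$shares)
  cat("  InsP5 shares (baseline-corrected):\n")
  cat(paste0("  ", sh, collapse = "\n"), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classification result
#'
#' @param x A `phyt_classification`.
#' @param ... Unused.
#' @return The evidence tibble with the label attached.
#' @method tidy phyt_classification
#' @export
tidy.phyt_classification <- function(x, ...) {
  x$evidence %>% mutate(label = x$label, .before = 1)
}

#' @rdname tidy.phyt_classification
#' @method glance phyt_classification
#' @export
glance.phyt_classification <- function(x, ...) {
  tibble(
    label = x$label,
    dominant_class = x$dominant_class %||% NA_character_,
    insp6_remaining = x$evidence$value[x$evidence$metric == "insp6_remaining"],
    n_notes = length(x$notes)
  )
}

# ---- end-to-end screen -----------------------------------------------------------

#' Analyze a pair of chromatograms as a phytase screen
#'
#' The full interpretive pipeline on a day-0 / day-n chromatogram pair:
#' detect -> assign -> quantify on both traces, substrate QC on the day-0
#' profile, degradation extent, per-class differencing, and phytase-class
#' inference.
#'
#' @param chrom_0,chrom_n Chromatograms (`time_min`, `signal`) of the same
#'   sample series at the start and after incubation.
#' @param rt Retention table.
#' @param params Classifier thresholds ([classifier_params()]).
#' @param impurity_threshold Substrate QC threshold (default 0.10).
#' @param detect_args Extra arguments passed to [detect_peaks()].
#' @return Object of class `phyt_screen`: list with `qc`, `profile_0`,
#'   `profile_n`, `diff`, `insp6_remaining`, `classification`, `label`.
#' @export
analyze_screen <- function(chrom_0, chrom_n, rt = retention_table(),
                           params = classifier_params(),
                           impurity_threshold = 0.10, detect_args = list()) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", what, "': ", conditionMessage(e)))
    })
  }
  quantify_one <- function(chrom, what) {
    pk <- stage(paste0("detect_peaks[", what, "]"),
                do.call(detect_peaks, c(list(chrom), detect_args)))
    pk <- stage(paste0("integrate_and_assign[", what, "]"),
                integrate_and_assign(pk, chrom, rt))
    stage(paste0("quantify[", what, "]"),
          suppressWarnings(quantify(pk)))
  }
  p0 <- quantify_one(chrom_0, "t0")
  pn <- quantify_one(chrom_n, "tn")
  qc <- stage("substrate_qc", substrate_qc(p0, impurity_threshold))
  remaining <- stage("degradation_extent", degradation_extent(pn, p0))
  dif <- stage("diff_profiles", diff_profiles(pn, p0, params$theta_report))
  cls <- stage("classify_activity", classify_activity(pn, p0, params))
  structure(
    list(qc = qc, profile_0 = p0, profile_n = pn, diff = dif,
         insp6_remaining = remaining, classification = cls,
         label = cls$label),
    class = "phyt_screen"
  )
}

#' @export
print.phyt_screen <- function(x, ...) {
  cat("== phytase screen report ==\n")
  cat(sprintf("substrate QC: impurity %.1f%% -> %s\n",
              100 * x$qc$impurity, if (x$qc$pass) "PASS" else "FAIL"))
  cat(sprintf("InsP6 remaining: %.1f%%\n", 100 * x$insp6_remaining))
  cat("classification:", x$label, "\n")
  appeared <- x$diff %>% filter(.data$appeared)
  if (nrow(appeared)) {
    cat("classes appearing after incubation:\n")
    for (i in seq_len(nrow(appeared))) {
      cat(sprintf("  %-20s %.3f -> %.3f\n", appeared$class[i],
                  appeared$reference[i], appeared$test[i]))
    }
  }
  for (n in x$classification$notes) cat("note:", n, "\n")
  invisible(x)
}

#' @rdname tidy.phyt_classification
#' @method tidy phyt_screen
#' @export
tidy.phyt_screen <- function(x, ...) {
  x$diff %>% mutate(label = x$label, qc_pass = x$qc$pass)
}

#' @rdname tidy.phyt_classification
#' @method glance phyt_screen
#' @export
glance.phyt_screen <- function(x, ...) {
  tibble(
    label = x$label,
    qc_pass = x$qc$pass,
    impurity = x$qc$impurity,
    insp6_remaining = x$insp6_remaining
  )
}

#' Write a screen report as structured text and evidence TSV
#'
#' @param x A `phyt_screen`.
#' @param path Path of the text report; the evidence TSV is written alongside
#'   with suffix `_evidence.tsv`.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(x, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(c(
    "[qc]",
    sprintf("impurity: %.6g", x$qc$impurity),
    sprintf("pass: %s", tolower(as.character(x$qc$pass))),
    "",
    "[degradation]",
    sprintf("insp6_remaining: %.6g", x$insp6_remaining),
    "",
    "[classification]",
    sprintf("label: %s", x$label),
    sprintf("note: %s", x$classification$notes)
  ), con)
  close(con)
  ev_path <- sub("(\\.[a-zA-Z0-9]+)?$", "_evidence.tsv", path)
  readr::write_tsv(tidy(x$classification), ev_path)
  invisible(path)
}
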