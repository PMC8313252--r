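# build a normalized profile over the chromatographic universe from a few
# named fractions (remainder goes to InsP6 unless it is named)
profile_of <- function(...) {
  vals <- c(...)
  u <- chrom_class_universe()
  amt <- stats::setNames(numeric(length(u)), u)
  amt[names(vals)] <- vals
  if (!"InsP6" %in% names(vals)) amt["InsP6"] <- 1 - sum(vals)
  tibble::tibble(class = u, amount = unname(amt),
                 mole_fraction = unname(amt) / sum(amt))
}

test_that("substrate QC measures impurity against the threshold", {
  clean <- profile_of("InsP5 [1/3-OH]" = 0.05)
  qc <- substrate_qc(clean)
  expect_equal(qc$impurity, 0.05)
  expect_true(qc$pass)
  expect_equal(attr(qc, "impurity_classes")$class, "InsP5 [1/3-OH]")

  expect_equal(substrate_qc(profile_of("InsP6" = 1))$impurity, 0)

  dirty <- profile_of("InsP5 [1/3-OH]" = 0.1, "Pi/InsP1" = 0.1, "InsP3" = 0.05)
  expect_false(substrate_qc(dirty)$pass)
  expect_true(substrate_qc(dirty, impurity_threshold = 0.3)$pass)

  unnorm <- clean
  unnorm$mole_fraction <- unnorm$mole_fraction * 2
  expect_error(substrate_qc(unnorm), "not normalized")
})

test_that("profile differencing flags appearing classes", {
  a <- profile_of("InsP5 [1/3-OH]" = 0.05)
  d0 <- diff_profiles(a, a)
  expect_true(all(d0$delta == 0))
  expect_false(any(d0$appeared))

  # a 3-phytase-like change: more 1/3-OH and Pi, less InsP6
  b <- profile_of("InsP5 [1/3-OH]" = 0.12, "Pi/InsP1" = 0.07)
  d <- diff_profiles(b, a)
  expect_gt(d$delta[d$class == "InsP5 [1/3-OH]"], 0)
  expect_gt(d$delta[d$class == "Pi/InsP1"], 0)
  expect_true(d$appeared[d$class == "Pi/InsP1"])
  expect_false(d$appeared[d$class == "InsP5 [1/3-OH]"]) # present at t0 already

  mismatched <- a[a$class != "InsP2", ]
  expect_error(diff_profiles(mismatched, a), "universes differ")
})

test_that("degradation extent is the remaining InsP6 fraction", {
  a <- profile_of("InsP5 [1/3-OH]" = 0.05)
  expect_equal(degradation_extent(a, a), 1)
  gone <- profile_of("InsP6" = 0, "Pi/InsP1" = 1)
  expect_equal(degradation_extent(gone, a), 0)
  expect_error(degradation_extent(a, gone), "no InsP6")
  half <- a
  half$amount <- half$amount / 2
  expect_equal(degradation_extent(half, a), 0.5)
})

test_that("the rule cascade reproduces the reference isolate patterns", {
  t0 <- profile_of("InsP5 [1/3-OH]" = 0.05)

  # 3-phytase: modest InsP6 loss, 1/3-OH and Pi up
  eskape <- profile_of("InsP6" = 0.80, "InsP5 [1/3-OH]" = 0.13, "Pi/InsP1" = 0.07)
  expect_equal(classify_activity(eskape, t0)$label, "PHYTASE_3")

  # MINPP: dominant 4/6-OH, smaller 5-OH, trace 1/3-OH
  ac12 <- profile_of("InsP6" = 0.45, "InsP5 [4/6-OH]" = 0.30,
                     "InsP5 [5-OH]" = 0.06, "InsP5 [1/3-OH]" = 0.055,
                     "d/l-Ins(1,2,3,4)P4" = 0.05, "Pi/InsP1" = 0.085)
  expect_equal(classify_activity(ac12, t0)$label, "MINPP_LIKE")

  # AppA-type 6-phytase: 4/6-OH dominant, 5-OH below the gate
  ch <- profile_of("InsP6" = 0.30, "InsP5 [4/6-OH]" = 0.55,
                   "InsP5 [5-OH]" = 0.01, "Pi/InsP1" = 0.09)
  expect_equal(classify_activity(ch, t0)$label, "PHYTASE_4_6")

  # 5-phytase and the unassigned 2-position case
  p5 <- profile_of("InsP6" = 0.40, "InsP5 [5-OH]" = 0.5, "Pi/InsP1" = 0.05)
  expect_equal(classify_activity(p5, t0)$label, "PHYTASE_5")
  p2 <- profile_of("InsP6" = 0.40, "InsP5 [2-OH]" = 0.5, "Pi/InsP1" = 0.05)
  expect_equal(classify_activity(p2, t0)$label, "UNCLASSIFIED_2POS")

  # unchanged profile
  expect_equal(classify_activity(t0, t0)$label, "NO_ACTIVITY")

  # many InsP5 and InsP4 classes without dominance -> mixed community
  mixed <- profile_of("InsP6" = 0.30,
                      "InsP5 [1/3-OH]" = 0.15, "InsP5 [4/6-OH]" = 0.14,
                      "InsP5 [5-OH]" = 0.08,
                      "d/l-Ins(1,2,5,6)P4" = 0.06, "d/l-Ins(1,2,3,4)P4" = 0.05,
                      "Ins(2,4,5,6)P4" = 0.04, "InsP3" = 0.05,
                      "Pi/InsP1" = 0.13)
  res <- classify_activity(mixed, t0)
  expect_equal(res$label, "MIXED_COMMUNITY")
  expect_true(any(grepl("MINPP", res$notes))) # ambiguity is reported

  expect_error(
    classify_activity(mixed[mixed$class != "InsP5 [5-OH]", ],
                      t0[t0$class != "InsP5 [5-OH]", ]),
    "InsP5")
})

test_that("classification is invariant to scaling and Pi-pool handling", {
  t0 <- profile_of("InsP5 [1/3-OH]" = 0.05)
  tn <- profile_of("InsP6" = 0.45, "InsP5 [4/6-OH]" = 0.30,
                   "InsP5 [5-OH]" = 0.06, "InsP5 [1/3-OH]" = 0.055,
                   "Pi/InsP1" = 0.135)
  base <- classify_activity(tn, t0)$label

  scaled <- tn
  scaled$amount <- scaled$amount * 7
  scaled$mole_fraction <- scaled$mole_fraction * 7 # unnormalized on purpose
  t0s <- t0
  t0s$amount <- t0s$amount * 7
  expect_equal(classify_activity(scaled, t0s)$label, base)

  # recompute fractions with the Pi pool excluded from the denominator
  drop_pi <- function(p) {
    p$mole_fraction <- ifelse(p$class == "Pi/InsP1", 0, p$mole_fraction)
    p$mole_fraction <- p$mole_fraction / sum(p$mole_fraction)
    p$amount <- ifelse(p$class == "Pi/InsP1", 0, p$amount)
    p
  }
  expect_equal(classify_activity(drop_pi(tn), drop_pi(t0))$label, base)
})

test_that("pure presets classify as themselves across random rate constants", {
  expected <- c(bsubtilis_bpp = "PHYTASE_3",
                buttiauxella_appa = "PHYTASE_4_6",
                five_phytase = "PHYTASE_5",
                ac12_minpp = "MINPP_LIKE",
                pputida_null = "NO_ACTIVITY")
  withr::local_seed(404)
  substrate <- make_substrate("clean")
  for (rep in 1:20) {
    k <- stats::runif(1, 0.05, 0.4)
    for (nm in names(expected)) {
      e <- preset_enzyme(nm)
      if (e$k > 0) e$k <- k
      tc <- simulate_timecourse(community_model(e), substrate, times = c(0, 2))
      res <- classify_activity(class_profile(tc, 2), class_profile(tc, 0))
      expect_equal(res$label, unname(expected[nm]),
                   label = sprintf("%s at k=%.3f", nm, k))
    }
  }
})

test_that("labels are stable under chromatographic noise", {
  # full pipeline, noise scaled so the weakest diagnostic peak keeps S/N 20
  sc <- preset_scenario("ch1064")
  rt <- retention_table(include_extra_insp4 = TRUE)
  tc <- simulate_timecourse(sc$community, sc$substrate, times = sc$days)
  p0 <- class_profile(tc, 0)
  pn <- class_profile(tc, 2)
  h46 <- pn$amount[pn$class == "InsP5 [4/6-OH]"] / (0.25 * sqrt(2 * pi))
  noise_sd <- h46 / 20
  ch0_clean <- synthesize_chromatogram(p0, rt)
  hits <- 0
  for (s in 1:100) {
    ch0 <- synthesize_chromatogram(p0, rt, noise_sd = noise_sd, seed = 7000 + s)
    chn <- synthesize_chromatogram(pn, rt, noise_sd = noise_sd, seed = 8000 + s)
    rep <- analyze_screen(ch0, chn, rt)
    hits <- hits + (rep$label == "PHYTASE_4_6")
  }
  expect_gte(hits, 95)
})

test_that("analyze_screen assembles QC, differencing and classification", {
  rt <- retention_table()
  substrate <- make_substrate("clean")
  null_com <- community_model(preset_enzyme("pputida_null"))
  tc <- simulate_timecourse(null_com, substrate, times = c(0, 2))
  ch0 <- synthesize_chromatogram(class_profile(tc, 0), rt)
  ch2 <- synthesize_chromatogram(class_profile(tc, 2), rt)
  rep <- analyze_screen(ch0, ch2, rt)
  expect_equal(rep$label, "NO_ACTIVITY")
  expect_true(rep$qc$pass)
  expect_equal(rep$insp6_remaining, 1, tolerance = 1e-6)

  td <- tidy(rep)
  expect_true(all(c("class", "delta", "label") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$label, "NO_ACTIVITY")
  gc <- glance(rep$classification)
  expect_equal(gc$label, "NO_ACTIVITY")

  # stage names propagate with errors
  expect_error(analyze_screen(ch0[1:2, ], ch2, rt), "detect_peaks\\[t0\\]")

  path <- withr::local_tempfile(fileext = ".txt")
  write_screen_report(rep, path)
  expect_true(file.exists(path))
  expect_true(any(grepl("label: NO_ACTIVITY", readLines(path))))
  expect_true(file.exists(sub("\\.txt$", "_evidence.tsv", path)))
})
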