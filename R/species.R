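#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr %>% mutate filter arrange select bind_rows group_by
#'   summarise ungroup left_join pull distinct across all_of rename n row_number
#' @importFrom rlang .data abort
#' @importFrom purrr map map_chr map_int map_dbl map_lgl pmap imap
NULL

# ---- phosphorylation states of the myo-inositol ring -------------------------
#
# A species is the set of ring carbons (1..6) bearing phosphate. Internally a
# species is an integer vector of sorted positions; its key is the digits
# pasted together ("" = free inositol, "123456" = InsP6). There are 2^6 = 64
# species; the chromatographic method cannot distinguish a species from its
# mirror image under the myo ring symmetry 1<->3, 4<->6 (2 and 5 fixed).

#' Validate and normalize a species position set
#'
#' @param positions Integer vector of ring positions in 1..6 (duplicates
#'   removed), or a species key string such as `"1245"`.
#' @return Sorted integer vector of positions.
#' @examples
#' as_species(c(4, 1, 2))
#' as_species("123456")
#' @export
as_species <- function(positions) {
  if (is.character(positions)) {
    stopifnot(length(positions) == 1)
    if (nchar(positions) == 0) return(integer(0))
    positions <- as.integer(strsplit(positions, "")[[1]])
  }
  positions <- unique(as.integer(positions))
  if (length(positions) && (anyNA(positions) || any(positions < 1L | positions > 6L))) {
    abort("invalid species: positions must be ring carbons in 1..6")
  }
  sort(positions)
}

#' Species key string
#'
#' @param positions Positions (any form accepted by [as_species()]).
#' @return Single string, digits of the sorted positions ("" for InsP0).
#' @export
species_key <- function(positions) {
  paste(as_species(positions), collapse = "")
}

#' Mirror image of a species under the myo ring symmetry
#'
#' The myo-inositol ring has a mirror plane through carbons 2 and 5, mapping
#' 1<->3 and 4<->6. Two phosphorylation states related by this involution are
#' enantiomers and co-elute on the HPLC gradient.
#'
#' @param positions Positions (any form accepted by [as_species()]).
#' @return Sorted integer vector: the mirror-image position set.
#' @examples
#' mirror_image(c(1, 2, 4)) # 2 3 6
#' @export
mirror_image <- function(positions) {
  s <- as_species(positions)
  sigma <- c(3L, 2L, 1L, 6L, 5L, 4L)
  sort(sigma[s])
}

# all 64 species, deterministic order: by level, then numeric key
all_species_keys <- function() {
  keys <- character(64)
  i <- 0L
  for (lev in 0:6) {
    sets <- utils::combn(6, lev, simplify = FALSE)
    if (lev == 0) sets <- list(integer(0))
    for (s in sets) {
      i <- i + 1L
      keys[i] <- paste(s, collapse = "")
    }
  }
  keys
}

#' All 64 phosphorylation states
#'
#' @return Tibble with one row per species: `key`, `level` (number of
#'   phosphates), `positions` (list of integer vectors).
#' @export
species_table <- function() {
  keys <- all_species_keys()
  tibble(
    key = keys,
    level = nchar(keys),
    positions = map(keys, as_species)
  )
}

# canonical orbit representative: lexicographically smallest key
orbit_rep_key <- function(s) {
  s <- as_species(s)
  k1 <- paste(s, collapse = "")
  k2 <- paste(mirror_image(s), collapse = "")
  if (k2 < k1) k2 else k1
}

#' Name a species or chromatographic class
#'
#' InsP6 and InsP0 get their common names; InsP5 classes are named by the
#' unphosphorylated position ("InsP5 \[4/6-OH\]"); all other classes are named
#' "Ins(p1,p2,...)Pn" using the orbit member with the lexicographically
#' smallest locant sequence, prefixed "d/l-" for enantiomeric pairs.
#'
#' @param positions Positions (any form accepted by [as_species()]).
#' @return Canonical class name (species map to their orbit's name).
#' @examples
#' name_species("2345") # "d/l-Ins(1,2,5,6)P4"
#' name_species("12345") # "InsP5 [6-OH]" is reported as "InsP5 [4/6-OH]"
#' @export
name_species <- function(positions) {
  s <- as_species(positions)
  lev <- length(s)
  if (lev == 6L) return("InsP6")
  if (lev == 0L) return("Ins")
  if (lev == 5L) {
    missing_pos <- setdiff(1:6, s)
    lab <- switch(as.character(missing_pos),
      "1" = , "3" = "1/3",
      "4" = , "6" = "4/6",
      as.character(missing_pos)
    )
    return(paste0("InsP5 [", lab, "-OH]"))
  }
  rep_key <- orbit_rep_key(s)
  rep_pos <- as_species(rep_key)
  is_meso <- identical(s, mirror_image(s))
  paste0(
    if (is_meso) "" else "d/l-",
    "Ins(", paste(rep_pos, collapse = ","), ")P", lev
  )
}

#' Chromatographic class of a species
#'
#' Returns the equivalence class a species falls into on the HPLC gradient:
#' its orbit under the ring mirror symmetry or, with `lumping = TRUE`, the
#' single per-level class at levels 3 and below (the gradient resolves only
#' one InsP3 peak and the low-phosphate region is pooled).
#'
#' @param positions Positions (any form accepted by [as_species()]).
#' @param lumping Collapse levels <= 3 to one class per level (default TRUE).
#' @return One-row tibble: `canonical_name`, `level`, `members`
#'   (list of member keys), `is_meso`, `lumped`.
#' @export
classify_species <- function(positions, lumping = TRUE) {
  s <- as_species(positions)
  lev <- length(s)
  if (lumping && lev <= 3L) {
    tab <- species_table() %>% filter(.data$level == lev)
    return(tibble(
      canonical_name = lumped_level_name(lev),
      level = lev,
      members = list(tab$key),
      is_meso = FALSE,
      lumped = TRUE
    ))
  }
  m <- mirror_image(s)
  meso <- identical(s, m)
  members <- unique(c(paste(s, collapse = ""), paste(m, collapse = "")))
  members <- sort(members)
  tibble(
    canonical_name = name_species(s),
    level = lev,
    members = list(members),
    is_meso = meso,
    lumped = FALSE
  )
}

lumped_level_name <- function(level) {
  switch(as.character(level),
    "0" = "Ins",
    "1" = "InsP1",
    "2" = "InsP2",
    "3" = "InsP3",
    stop("no lumped class above level 3")
  )
}

#' Enumerate chromatographic classes
#'
#' All mirror-symmetry orbits at the requested level(s), in a deterministic
#' canonical order (by level descending, then by the orbit representative's
#' locant sequence). Without lumping there are 1/4/9/12/9/4/1 classes at
#' levels 6..0 (40 in total); with lumping levels 3 and below collapse to one
#' class per level.
#'
#' @param level Integer 0..6, or NULL (default) for all levels.
#' @param lumping Collapse levels <= 3 (default FALSE for enumeration).
#' @return Tibble: `level`, `canonical_name`, `members` (list of member
#'   keys), `is_meso`, `lumped`; one row per class.
#' @examples
#' enumerate_classes(5) # the four InsP5 classes
#' nrow(enumerate_classes()) # 40
#' @export
enumerate_classes <- function(level = NULL, lumping = FALSE) {
  if (!is.null(level)) {
    level <- as.integer(level)
    if (length(level) != 1 || is.na(level) || level < 0L || level > 6L) {
      abort("level must be a single integer in 0..6")
    }
  }
  levels_wanted <- if (is.null(level)) 6:0 else level
  out <- list()
  for (lev in levels_wanted) {
    if (lumping && lev <= 3L) {
      tab <- species_table() %>% filter(.data$level == lev)
      out[[length(out) + 1L]] <- tibble(
        level = lev,
        canonical_name = lumped_level_name(lev),
        members = list(tab$key),
        is_meso = FALSE,
        lumped = TRUE
      )
      next
    }
    keys <- species_table() %>%
      filter(.data$level == lev) %>%
      pull("key")
    reps <- sort(unique(map_chr(keys, orbit_rep_key)))
    out[[length(out) + 1L]] <- bind_rows(map(reps, function(k) {
      cl <- classify_species(k, lumping = FALSE)
      cl$level <- lev
      cl
    })) %>% select("level", "canonical_name", "members", "is_meso", "lumped")
  }
  bind_rows(out)
}

#' Export a class listing to TSV
#'
#' @param classes Tibble from [enumerate_classes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_class_listing <- function(classes, path) {
  flat <- classes %>%
    mutate(members = map_chr(.data$members, paste, collapse = "/")) %>%
    select("level", "canonical_name", "members", "is_meso", "lumped")
  readr::write_tsv(flat, path)
  invisible(path)
}

# class name per species, aligned with species_table() row order
species_class_map <- function(lumping = TRUE) {
  tab <- species_table()
  map_chr(tab$key, function(k) {
    classify_species(k, lumping = lumping)$canonical_name
  })
}

# ---- degradation graph -------------------------------------------------------

#' The phytate degradation graph
#'
#' The DAG over all 64 phosphorylation states whose edges remove one phosphate:
#' (S, S \ {p}) for every p in S, labelled by the removed position. Every
#' maximal path runs InsP6 -> free inositol in six steps.
#'
#' @return List with `nodes` (the [species_table()]) and `edges`, a tibble
#'   `from`, `to` (species keys) and `removed` (ring position).
#' @export
degradation_graph <- function() {
  tab <- species_table()
  edges <- bind_rows(map(tab$key, function(k) {
    s <- as_species(k)
    if (!length(s)) return(NULL)
    tibble(
      from = k,
      to = map_chr(s, function(p) paste(setdiff(s, p), collapse = "")),
      removed = s
    )
  }))
  list(nodes = tab, edges = edges)
}
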