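# Structured (YAML) configuration files for enzymes, communities and
# scenarios, so screens can be defined outside R code. Units: weights are
# dimensionless preferences, rates per day, times in days.

community_to_list <- function(community) {
  list(
    enzymes = lapply(seq_along(community$enzymes), function(i) {
      e <- community$enzymes[[i]]
      list(name = e$name, class_label = e$class_label,
           w = as.numeric(e$weights), k = e$k, mix = community$mix[i])
    }),
    sorption = community$sorption_rate,
    pi_uptake = community$pi_uptake_rate,
    t_lag = community$t_lag,
    tau = community$tau
  )
}

community_from_list <- function(x) {
  enzymes <- lapply(x$enzymes, function(e) {
    enzyme_model(e$name, as.numeric(e$w), e$k,
                 class_label = e$class_label %||% "GENERIC")
  })
  community_model(
    enzymes = enzymes,
    mix = vapply(x$enzymes, function(e) e$mix %||% 1, 0),
    sorption_rate = x$sorption %||% 0,
    pi_uptake_rate = x$pi_uptake %||% 0,
    t_lag = x$t_lag %||% 0,
    tau = x$tau %||% 0.25
  )
}

#' Read / write community definitions as YAML config files
#'
#' The config carries, per enzyme: `name`, `class_label`, `w` (six position
#' weights), `k` (per day), `mix`; plus community-level `sorption`,
#' `pi_uptake`, `t_lag`, `tau` (days).
#'
#' @param community A [community_model()].
#' @param path File path.
#' @return `read_community_config`: a `phyt_community`;
#'   `write_community_config`: the path, invisibly.
#' @export
write_community_config <- function(community, path) {
  yaml::write_yaml(community_to_list(community), path)
  invisible(path)
}

#' @rdname write_community_config
#' @export
read_community_config <- function(path) {
  community_from_list(yaml::read_yaml(path))
}

#' Read / write full scenario config files
#'
#' A scenario config holds `name`, `substrate` (named mole fractions),
#' `days`, `noise` (baseline, sd), `seed` and the inline `community` block of
#' [write_community_config()].
#'
#' @param scenario A scenario, e.g. from [preset_scenario()].
#' @param path File path.
#' @return `read_scenario_config`: a `phyt_scenario`;
#'   `write_scenario_config`: the path, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  sub <- scenario$substrate
  sub <- sub[sub$amount > 0, ]
  yaml::write_yaml(list(
    name = scenario$name,
    substrate = stats::setNames(as.list(sub$amount), sub$class),
    days = as.numeric(scenario$days),
    noise = scenario$noise,
    seed = scenario$seed,
    community = community_to_list(scenario$community)
  ), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  substrate <- make_substrate(unlist(x$substrate))
  days <- as.numeric(x$days)
  if (!0 %in% days) abort("scenario days must include 0")
  structure(
    list(name = x$name %||% "custom", substrate = substrate,
         community = community_from_list(x$community),
         days = days,
         noise = list(baseline = x$noise$baseline %||% 0,
                      sd = x$noise$sd %||% 0),
         seed = as.integer(x$seed %||% 1L)),
    class = "phyt_scenario"
  )
}
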