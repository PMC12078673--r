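#' Build and validate a scenario configuration
#'
#' A scenario bundles everything needed to run the pipeline: the upstream
#' discharge value(s), the age classes, the bias parameters, the suitability
#' curve library and the Strahler-order attribute table. Unknown fields are
#' rejected so config typos fail loudly.
#'
#' @param q0 positive upstream discharge (m^3/s); a vector defines a sweep.
#' @param age_classes character vector out of `c("adult", "juvenile")`.
#' @param bias a `bias_parameters` object.
#' @param hsc_library an `hsc_library`.
#' @param so_table Strahler attribute table (see [generate_so_table()]); may
#'   be `NULL` if the network carries its own attributes.
#' @param boundary kernel boundary policy, `"reflect"` or `"absorb-self"`.
#' @param seed integer seed for any stochastic downstream step.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(q0 = 0.2,
                            age_classes = c("adult", "juvenile"),
                            bias = bias_parameters(),
                            hsc_library = default_hsc_library(),
                            so_table = generate_so_table(8),
                            boundary = c("reflect", "absorb-self"),
                            seed = 1L) {
  boundary <- match.arg(boundary)
  if (any(q0 <= 0)) stop("q0 values must be positive")
  if (length(age_classes) == 0 ||
      !all(age_classes %in% c("adult", "juvenile"))) {
    stop("age_classes must be a non-empty subset of {adult, juvenile}")
  }
  stopifnot(inherits(bias, "bias_parameters"),
            inherits(hsc_library, "hsc_library"))
  structure(
    list(q0 = as.numeric(q0), age_classes = age_classes, bias = bias,
         hsc_library = hsc_library, so_table = so_table,
         boundary = boundary, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' Recognized keys: `q0` (number or list), `age_classes`, `boundary`, `seed`,
#' `bias` (sub-keys `b0_magnitude`, `b_min_mult`, `b_max_mult`, `a`,
#' `sign_convention`, `hsi_floor`), `hsc_library` (path to an HSC YAML file),
#' and `so_table` (list with `max_so`, `base`, `width_factor`,
#' `slope_factor`). Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("q0", "age_classes", "boundary", "seed", "bias",
             "hsc_library", "so_table")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  args <- list()
  if (!is.null(raw$q0)) args$q0 <- unlist(raw$q0)
  if (!is.null(raw$age_classes)) args$age_classes <- unlist(raw$age_classes)
  if (!is.null(raw$boundary)) args$boundary <- raw$boundary
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$bias)) {
    known_b <- c("b0_magnitude", "b_min_mult", "b_max_mult", "a",
                 "sign_convention", "hsi_floor")
    extra_b <- setdiff(names(raw$bias), known_b)
    if (length(extra_b)) {
      stop("unknown bias key(s): ", paste(extra_b, collapse = ", "))
    }
    args$bias <- do.call(bias_parameters, raw$bias)
  }
  if (!is.null(raw$hsc_library)) {
    args$hsc_library <- read_hsc_library(raw$hsc_library)
  }
  if (!is.null(raw$so_table)) {
    st <- raw$so_table
    args$so_table <- generate_so_table(
      max_so = st$max_so,
      base = if (is.null(st$base)) c(2.0, 0.02, 0.04) else unlist(st$base),
      width_factor = if (is.null(st$width_factor)) 1.6 else st$width_factor,
      slope_factor = if (is.null(st$slope_factor)) 0.6 else st$slope_factor
    )
  }
  do.call(scenario_config, args)
}

#' Serialize a scenario configuration to YAML
#'
#' Inverse of [read_scenario_config()] for the scalar fields; the HSC library
#' is written to a sibling file and referenced by path.
#'
#' @param config a `scenario_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  hsc_path <- file.path(dirname(path), "hsc_library.yaml")
  write_hsc_library(config$hsc_library, hsc_path)
  st <- config$so_table
  out <- list(
    q0 = as.list(config$q0),
    age_classes = as.list(config$age_classes),
    boundary = config$boundary,
    seed = config$seed,
    bias = list(
      b0_magnitude = config$bias$b0_magnitude,
      b_min_mult = config$bias$b_min / config$bias$b0_magnitude,
      b_max_mult = config$bias$b_max / config$bias$b0_magnitude,
      a = config$bias$a,
      sign_convention = config$bias$sign_convention,
      hsi_floor = config$bias$hsi_floor
    ),
    hsc_library = hsc_path,
    so_table = list(
      max_so = max(st$SO),
      base = as.list(c(st$B_m[1], st$S[1], st$n[1])),
      width_factor = if (nrow(st) > 1) st$B_m[2] / st$B_m[1] else 1,
      slope_factor = if (nrow(st) > 1) st$S[2] / st$S[1] else 1
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write an HSC library to YAML
#'
#' @param lib an `hsc_library`.
#' @param path output YAML path.
#' @export
write_hsc_library <- function(lib, path) {
  stopifnot(inherits(lib, "hsc_library"))
  out <- lapply(lib, function(block) {
    lapply(block, function(co) {
      u <- unclass(co)
      u[!vapply(u, is.null, logical(1))]
    })
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full eco-hydraulic pipeline for one network
#'
#' For every combination of discharge scenario and age class: routes the
#' discharge, solves normal-flow hydraulics, evaluates the suitability
#' curves, computes the habitat-weighted biases and movement probabilities,
#' and summarizes the compound HSI over the network (mean and population
#' standard deviation).
#'
#' @param net a `river_network` (attributes may be pre-assigned or come from
#'   the config's Strahler table).
#' @param config a `scenario_config`.
#' @return list with `results` (one data.frame per node per scenario and age
#'   class, all scenarios stacked) and `summary` (one row per scenario and
#'   age class: `q0`, `age_class`, `mean_hsi_c`, `sd_hsi_c`).
#' @export
run_scenario <- function(net, config = scenario_config()) {
  stopifnot(inherits(net, "river_network"),
            inherits(config, "scenario_config"))
  if (!is.null(config$so_table)) {
    net <- assign_reach_attributes(net, config$so_table)
  }
  results <- list()
  summaries <- list()
  for (q0 in config$q0) {
    q <- route_discharge(net, q0)
    hyd <- network_hydraulics(net, q)
    for (age in config$age_classes) {
      hsi <- network_hsi(net, hyd, config$hsc_library, age)
      bias <- network_bias(net, hsi, config$bias, age)
      tab <- data.frame(
        q0 = q0,
        id = net$nodes$id,
        SO = net$nodes$strahler_order,
        age_class = age,
        Q_m3s = hyd$Q_m3s[match(net$nodes$id, hyd$id)],
        H_m = hyd$H_m[match(net$nodes$id, hyd$id)],
        U_ms = hyd$U_ms[match(net$nodes$id, hyd$id)],
        stringsAsFactors = FALSE
      )
      m <- match(net$nodes$id, hsi$id)
      tab$hsi_h <- hsi$hsi_h[m]
      tab$hsi_u <- hsi$hsi_u[m]
      tab$hsi_c <- hsi$hsi_c[m]
      mb <- match(net$nodes$id, bias$id)
      for (col in c("b_up1", "b_up2", "p_up1", "p_up2", "p_dn")) {
        tab[[col]] <- bias[[col]][mb]
      }
      results[[length(results) + 1L]] <- tab
      summaries[[length(summaries) + 1L]] <- data.frame(
        q0 = q0, age_class = age,
        mean_hsi_c = mean(tab$hsi_c),
        sd_hsi_c = stats::sd(tab$hsi_c) *
          sqrt((nrow(tab) - 1) / nrow(tab))  # population SD
      )
    }
  }
  list(results = do.call(rbind, results),
       summary = do.call(rbind, summaries))
}

#' Write scenario results to CSV files
#'
#' Writes `results.csv` and `summary.csv` into `dir` at full precision.
#'
#' @param scenario output of [run_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario_csv <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(scenario$results, file.path(dir, "results.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(scenario$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
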