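#' Read a cohort manifest
#'
#' @param path TSV with columns `subject_id`, `group`, `timepoint`,
#'   `path` (series CSV, relative paths resolved against the manifest's
#'   directory).
#' @return Data frame with absolute `path` column.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "timepoint", "path")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  if (anyDuplicated(man[c("subject_id", "timepoint")])) {
    stop("duplicate subject_id x timepoint rows in manifest", call. = FALSE)
  }
  man
}

#' Read one region time-series CSV
#'
#' @param path CSV with a header of region labels, one row per time
#'   sample.
#' @param subject_id,group,timepoint Metadata labels.
#' @param regions Optional [region_set()]; when given, the file's columns
#'   must match its labels in order.
#' @return A [subject_ts()].
#' @export
read_subject_ts <- function(path, subject_id, group, timepoint,
                            regions = NULL) {
  if (!file.exists(path)) {
    stop("series file not found: ", path, call. = FALSE)
  }
  dat <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(regions) && !identical(names(dat), regions$label)) {
    stop("region columns of ", basename(path),
         " do not match the region set", call. = FALSE)
  }
  subject_ts(as.matrix(dat), subject_id, group, timepoint)
}

#' Default contrast set for the two-group, two-timepoint design
#'
#' The four comparisons of the longitudinal case-control design: genotype
#' at each timepoint (unpaired) and timepoint within each genotype
#' (paired). Each contrast gets its own seed derived from `seed`.
#'
#' @param groups Two cohort labels (first = case cohort, reported as
#'   side_a of the genotype contrasts).
#' @param timepoints Two timepoint labels, in chronological order; the
#'   longitudinal contrasts report later minus earlier.
#' @param n_perm,alpha,ci_level,fdr_family Passed to [contrast()].
#' @param seed Master seed.
#' @return Named list of [contrast()] specs.
#' @export
default_contrasts <- function(groups = c("TG", "WT"),
                              timepoints = c("4M", "6M"),
                              n_perm = 10000, alpha = 0.05,
                              ci_level = 95, fdr_family = "joint",
                              seed = 1L) {
  stopifnot(length(groups) == 2, length(timepoints) == 2)
  mk <- function(kind, a, b, k) {
    contrast(kind, a, b, n_perm = n_perm, alpha = alpha,
             ci_level = ci_level, fdr_family = fdr_family,
             seed = as.integer(seed) + k)
  }
  cs <- list(
    mk("unpaired", list(group = groups[1], timepoint = timepoints[1]),
       list(group = groups[2], timepoint = timepoints[1]), 1L),
    mk("unpaired", list(group = groups[1], timepoint = timepoints[2]),
       list(group = groups[2], timepoint = timepoints[2]), 2L),
    mk("paired", list(group = groups[1], timepoint = timepoints[2]),
       list(group = groups[1], timepoint = timepoints[1]), 3L),
    mk("paired", list(group = groups[2], timepoint = timepoints[2]),
       list(group = groups[2], timepoint = timepoints[1]), 4L)
  )
  stats::setNames(cs, vapply(cs, `[[`, character(1), "name"))
}

# Drop subjects missing a timepoint from a paired contrast; returns the
# kept profiles plus the excluded subject ids (reported, never silent).
pair_complete <- function(profiles, spec) {
  sel_a <- select_profiles(profiles, spec$side_a)
  sel_b <- select_profiles(profiles, spec$side_b)
  ids_a <- vapply(sel_a, function(p) p$subject_id, character(1))
  ids_b <- vapply(sel_b, function(p) p$subject_id, character(1))
  common <- intersect(ids_a, ids_b)
  dropped <- sort(setdiff(union(ids_a, ids_b), common))
  keep <- c(sel_a[ids_a %in% common], sel_b[ids_b %in% common])
  list(profiles = keep, dropped = dropped)
}

#' Run the full analysis pipeline
#'
#' Manifest (or in-memory cohort) to contrast tables: reads and validates
#' every series, computes each subject's weighted connectivity matrix and
#' nodal-degree profile over the density grid, then runs every requested
#' permutation contrast. Paired contrasts silently drop nothing: subjects
#' missing a timepoint are excluded with a warning and listed in the run
#' report.
#'
#' @param manifest Path to a manifest TSV, or a cohort list as returned
#'   by [generate_cohort()].
#' @param regions A [region_set()] (default [dmln_regions()]).
#' @param densities Density grid in percent.
#' @param contrasts List of [contrast()] specs (default
#'   [default_contrasts()] with `seed`).
#' @param n_perm,alpha Convenience overrides applied to the default
#'   contrasts.
#' @param seed Master seed for the default contrast set.
#' @param out_dir If non-`NULL`, write one TSV per contrast, a long-format
#'   profile TSV and a JSON run report there.
#'
#' @return A list of class `nd_run`: `results` (named list of
#'   `nd_contrast` tables), `profiles`, `regions`, `report`.
#' @examples
#' spec <- cohort_spec(n_group_a = 3, n_group_b = 3, n_regions = 5,
#'                     n_timepoints = 60)
#' run <- run_pipeline(generate_cohort(spec), densities = c(20, 30),
#'                     n_perm = 200, seed = 7)
#' names(run$results)
#' @export
run_pipeline <- function(manifest, regions = NULL,
                         densities = density_grid(), contrasts = NULL,
                         n_perm = 10000, alpha = 0.05, seed = 1L,
                         out_dir = NULL) {
  if (is.character(manifest)) {
    man <- read_manifest(manifest)
    if (is.null(regions)) regions <- dmln_regions()
    series <- Map(read_subject_ts, man$path, man$subject_id, man$group,
                  man$timepoint, MoreArgs = list(regions = regions))
  } else if (is.list(manifest) && !is.null(manifest$series)) {
    man <- manifest$manifest
    if (is.null(regions)) regions <- manifest$regions
    series <- manifest$series
  } else {
    stop("`manifest` must be a TSV path or a generate_cohort() result",
         call. = FALSE)
  }
  for (ts in series) {
    if (ncol(ts$data) != nrow(regions)) {
      stop("series ", ts$subject_id, "_", ts$timepoint, " has ",
           ncol(ts$data), " regions, expected ", nrow(regions),
           call. = FALSE)
    }
  }
  if (is.null(contrasts)) {
    groups <- unique(man$group)
    tps <- unique(man$timepoint)
    contrasts <- if (length(tps) >= 2) {
      default_contrasts(groups, tps[1:2], n_perm = n_perm, alpha = alpha,
                        seed = seed)
    } else {
      ct <- contrast("unpaired", list(group = groups[1], timepoint = tps),
                     list(group = groups[2], timepoint = tps),
                     n_perm = n_perm, alpha = alpha,
                     seed = as.integer(seed) + 1L)
      stats::setNames(list(ct), ct$name)
    }
  }
  if (length(contrasts) == 0) stop("no contrasts requested", call. = FALSE)

  profiles <- cohort_profiles(series, densities)

  results <- list()
  exclusions <- list()
  for (ct in contrasts) {
    use <- profiles
    if (ct$kind == "paired") {
      pc <- pair_complete(profiles, ct)
      use <- pc$profiles
      if (length(pc$dropped)) {
        warning("contrast ", ct$name, ": excluded subject(s) missing a ",
                "timepoint: ", paste(pc$dropped, collapse = ", "),
                call. = FALSE)
        exclusions[[ct$name]] <- pc$dropped
      }
    }
    results[[ct$name]] <- permutation_test(use, ct, regions = regions)
  }

  cell_counts <- as.data.frame(table(group = man$group,
                                     timepoint = man$timepoint),
                               stringsAsFactors = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("ndgraph")),
    r_version = R.version.string,
    seed = seed,
    n_regions = nrow(regions),
    densities = densities,
    manifest_rows = nrow(man),
    cell_counts = cell_counts,
    contrasts = lapply(contrasts, function(ct) {
      list(name = ct$name, kind = ct$kind, n_perm = ct$n_perm,
           alpha = ct$alpha, ci_level = ct$ci_level, seed = ct$seed,
           fdr_family = ct$fdr_family,
           excluded_subjects = exclusions[[ct$name]])
    })
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(results)) {
      utils::write.table(results[[nm]],
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    utils::write.table(profiles_to_long(profiles),
                       file.path(out_dir, "nd_profiles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(results = results, profiles = profiles,
                 regions = regions, report = report),
            class = "nd_run")
}

#' Read a run configuration file
#'
#' YAML (or JSON) mirror of the [run_pipeline()] arguments, plus optional
#' `synthetic`, `model` and `effects` blocks that are forwarded to
#' [cohort_spec()], [network_model()] and [effect_spec()].
#'
#' @param path Config file.
#' @return A named list of parsed fields.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  cfg
}

#' Run the pipeline from a config file
#'
#' @param config Path to a YAML/JSON config, or an equivalent list. Keys:
#'   `manifest` or `synthetic` (+ optional `model`, `effects`),
#'   `densities` (`min`, `max`, `step`), `n_perm`, `alpha`, `seed`,
#'   `out_dir`.
#' @return The [run_pipeline()] result.
#' @export
run_from_config <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dens <- if (is.null(cfg$densities)) density_grid() else
    density_grid(cfg$densities$min, cfg$densities$max,
                 if (is.null(cfg$densities$step)) 1 else cfg$densities$step)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  n_perm <- if (is.null(cfg$n_perm)) 10000 else cfg$n_perm
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  if (!is.null(cfg$manifest)) {
    input <- cfg$manifest
  } else if (!is.null(cfg$synthetic)) {
    spec <- do.call(cohort_spec, c(cfg$synthetic, list(seed = seed)))
    model <- if (is.null(cfg$model)) NULL else
      do.call(network_model,
              c(cfg$model, list(n_regions = spec$n_regions)))
    effects <- lapply(cfg$effects, function(e) do.call(effect_spec, e))
    input <- generate_cohort(spec, model = model, effects = effects,
                             dir = cfg$data_dir)
  } else {
    stop("config needs either `manifest` or `synthetic`", call. = FALSE)
  }
  run_pipeline(input, densities = dens, n_perm = n_perm, alpha = alpha,
               seed = seed, out_dir = cfg$out_dir)
}
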