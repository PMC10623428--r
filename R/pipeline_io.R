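# Tidy CSV schemas, configuration and run manifests binding the pipeline
# stages together. Files store time in minutes (as measured); the package
# works in hours internally, converting only at this boundary.

.schemas <- list(
  tolerance = c("animal_id", "group", "test_kind", "week", "time_min",
                "glucose_mgdl"),
  feeding = c("group", "week", "food_g", "group_mass_g"),
  hormone = c("animal_id", "group", "fasting_glucose_mgdl",
              "fasting_insulin_ng_ml"),
  adipocyte = c("animal_id", "group", "area_um2"),
  peaks = c("sample_id", "group", "replicate", "mz", "intensity")
)

.read_schema <- function(path, kind, numeric_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- .schemas[[kind]]
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(kind, " CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))
    if (length(bad)) {
      stop(kind, " CSV '", path, "': malformed or missing '", col,
           "' in row(s) ", paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
    df[[col]] <- as.numeric(v)
  }
  df
}

#' Read a tolerance-test CSV
#'
#' Expects minute-labelled times (\code{time_min} column); a file carrying an
#' hour-labelled time column is rejected rather than silently converted.
#' Times are converted to hours on ingestion (240 min becomes 4 h) in the
#' added \code{time_h} column.
#'
#' @param path CSV path with columns \code{animal_id, group, test_kind,
#'   week, time_min, glucose_mgdl} (extra columns are kept).
#' @return data.frame with an additional \code{time_h} column.
#' @export
read_tolerance_csv <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1))
  if ("time_h" %in% header && !"time_min" %in% header) {
    stop("unit mismatch: '", path, "' carries hour-labelled times; ",
         "tolerance CSVs must store time_min (minutes)")
  }
  df <- .read_schema(path, "tolerance", c("week", "time_min", "glucose_mgdl"))
  df$time_h <- df$time_min / 60
  df
}

#' Write a tolerance-test CSV
#' @param df tolerance-test data.frame (a \code{time_h} column is dropped;
#'   minutes are the on-disk unit).
#' @param path output path.
#' @export
write_tolerance_csv <- function(df, path) {
  df$time_h <- NULL
  stopifnot(all(.schemas$tolerance %in% names(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the feeding, hormone, adipocyte and peak-list CSVs
#'
#' Schema-validated readers: missing columns or malformed numeric cells are
#' rejected with the offending rows named.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feeding_csv <- function(path) {
  .read_schema(path, "feeding", c("week", "food_g", "group_mass_g"))
}

#' @rdname read_feeding_csv
#' @export
read_hormone_csv <- function(path) {
  .read_schema(path, "hormone",
               c("fasting_glucose_mgdl", "fasting_insulin_ng_ml"))
}

#' @rdname read_feeding_csv
#' @export
read_adipocyte_csv <- function(path) {
  .read_schema(path, "adipocyte", "area_um2")
}

#' @rdname read_feeding_csv
#' @export
read_peaks_csv <- function(path) {
  .read_schema(path, "peaks", c("mz", "intensity"))
}

#' @rdname read_feeding_csv
#' @param df data.frame to write.
#' @param kind one of \code{"feeding"}, \code{"hormone"}, \code{"adipocyte"},
#'   \code{"peaks"}.
#' @export
write_table_csv <- function(df, path, kind) {
  stopifnot(kind %in% names(.schemas), all(.schemas[[kind]] %in% names(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write every table of a synthetic cohort
#'
#' Writes the tolerance-test, feeding, hormone, adipocyte and peak-list CSVs
#' plus a run manifest into a directory.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tolerance = file.path(dir, "tolerance_tests.csv"),
    feeding = file.path(dir, "feeding.csv"),
    hormone = file.path(dir, "hormones.csv"),
    adipocyte = file.path(dir, "adipocytes.csv"),
    peaks = file.path(dir, "peaks.csv"))
  write_tolerance_csv(cohort$tolerance_tests, paths["tolerance"])
  write_table_csv(cohort$feeding, paths["feeding"], "feeding")
  write_table_csv(cohort$hormones, paths["hormone"], "hormone")
  write_table_csv(cohort$adipocytes, paths["adipocyte"], "adipocyte")
  write_table_csv(cohort$peaks, paths["peaks"], "peaks")
  manifest <- run_manifest(cohort$config, files = unname(paths))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a cohort configuration file
#'
#' Parses a YAML cohort description (see the commented template at
#' \code{system.file("extdata", "cohort_config.yaml", package = "metabodyn")})
#' into a [cohort_config()]. Fields omitted from the file keep the package
#' defaults; an optional \code{group_dynamics_csv} path replaces the bundled
#' group-true parameter fixture.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("interventions", "sexes", "n_per_group",
                        "gtt_grid_min", "itt_grid_min", "weeks", "gtt_weeks",
                        "itt_weeks", "noise_sd_mgdl", "animal_effect_cv",
                        "glucose_floor_mgdl", "ims", "seed"))]
  if (!is.null(y$group_dynamics_csv)) {
    args$group_dynamics <- utils::read.csv(y$group_dynamics_csv,
                                           stringsAsFactors = FALSE)
  }
  if (!is.null(args$ims)) {
    # YAML renders mixed int/float sequences as lists; flatten scalars
    args$ims <- lapply(args$ims, function(x) {
      if (is.list(x) && all(vapply(x, is.atomic, TRUE)) &&
          all(lengths(x) == 1L)) unlist(x) else x
    })
    if (!is.null(args$ims$effect_peaks)) {
      args$ims$effect_peaks <-
        as.data.frame(lapply(args$ims$effect_peaks, unlist))
    }
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(cohort_config, args)
}

#' Run manifest
#'
#' Captures the reproducibility envelope of a pipeline run: the configuration
#' hash, seed, package version, input/output file checksums and a timestamp.
#' Re-running a deterministic stage with identical config and inputs
#' reproduces identical checksums.
#'
#' @param config a [cohort_config()] (or any serialisable config object).
#' @param files character vector of file paths to checksum.
#' @return List with \code{config_hash}, \code{seed}, \code{package_version},
#'   \code{checksums}, \code{timestamp}.
#' @export
run_manifest <- function(config, files = character(0)) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  # drop volatile attributes before hashing
  cfg <- unclass(config)
  yaml::write_yaml(lapply(cfg, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }), tmp)
  sums <- if (length(files)) as.list(tools::md5sum(files)) else list()
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = if (!is.null(config$seed)) config$seed else NA,
       package_version = as.character(utils::packageVersion("metabodyn")),
       checksums = sums,
       timestamp = format(Sys.time(), tz = "UTC"))
}
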