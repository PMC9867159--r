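ANGIOSOMES <- c("MPA", "LPA", "MCA", "LCA")
REGION_CODES <- c(MPA = 1L, LPA = 2L, MCA = 3L, LCA = 4L)

region_variables <- function(table = ntr_class_table()) {
  c("mean", "std", "max", "min", "skew", "kurtosis", "ET", "HSE", table$ntr)
}

#' Feature name schema
#'
#' Enumerates the full set of feature names produced by
#' [extract_features()], in output order. Per foot ('L'/'R') and per region
#' (the four angiosomes plus the entire foot, which carries no region
#' descriptor): six summary statistics, ET, HSE and the ten NTR occupancy
#' fractions. Per foot, the whole-foot TCI. Per region, one footless ETD
#' feature (`Foot_ETD`, `MPA_ETD`, ...). With the default class table the
#' schema holds 187 names.
#'
#' @param table Class table defining the NTR feature names.
#' @return Character vector of feature names.
#' @export
feature_schema <- function(table = ntr_class_table()) {
  vars <- region_variables(table)
  names_out <- character(0)
  for (side in c("L", "R")) {
    for (region in c(ANGIOSOMES, "")) {
      prefix <- if (nzchar(region)) paste(side, region, sep = "_") else side
      names_out <- c(names_out, paste(prefix, vars, sep = "_"))
    }
    names_out <- c(names_out, paste(side, "TCI", sep = "_"))
  }
  c(names_out, paste(c("Foot", ANGIOSOMES), "ETD", sep = "_"))
}

foot_region_temps <- function(foot, region) {
  code <- if (region == "foot") which(foot$mask > 0L) else which(foot$mask == REGION_CODES[[region]])
  foot$grid[code]
}

extract_foot <- function(foot, side, table, refs) {
  out <- numeric(0)
  ets <- numeric(0)
  means <- numeric(0)
  for (region in c(ANGIOSOMES, "foot")) {
    temps <- foot_region_temps(foot, region)
    label <- if (region == "foot") sprintf("%s foot", side) else sprintf("%s_%s", side, region)
    if (length(temps) == 0) {
      stop(sprintf("region '%s' is empty", label))
    }
    stats <- summary_stats(temps, region = label)
    occ <- ntr_occupancy(temps, table, region = label)
    et <- estimated_temperature(occ, table)
    hse <- hot_spot_estimator(occ, table)
    prefix <- if (region == "foot") side else paste(side, region, sep = "_")
    vals <- c(stats, ET = et, HSE = hse, occ)
    names(vals) <- paste(prefix, c(names(stats), "ET", "HSE", table$ntr), sep = "_")
    out <- c(out, vals)
    if (region == "foot") {
      ets <- c(ets, Foot = et)
    } else {
      ets[region] <- et
      means[region] <- stats[["mean"]]
    }
  }
  tci <- thermal_change_index(means, refs)
  out <- c(out, stats::setNames(tci[["foot"]], paste(side, "TCI", sep = "_")))
  list(features = out, ets = ets)
}

#' Extract the full feature vector of a subject
#'
#' Computes every thermal feature of one subject: for each foot and each of
#' five regions (four angiosomes plus the entire foot) the six summary
#' statistics, the estimated temperature (ET), the hot spot estimator (HSE)
#' and the ten NTR occupancy fractions; per foot the whole-foot thermal
#' change index (TCI); and per region the unsigned inter-foot estimated
#' temperature difference (ETD). Feature names follow the standard
#' nomenclature: foot prefix `L`/`R`, then the angiosome (omitted for the
#' entire foot), then the variable (e.g. `R_LPA_min`, `L_MPA_NTR_C3`,
#' `Foot_ETD`).
#'
#' @param subject A subject record as built by [make_subject()] or
#'   [read_subject()]: a list with elements `left` and `right`, each a list
#'   with a temperature `grid` matrix (Celsius) and an integer `mask`
#'   matrix (0 background, 1 MPA, 2 LPA, 3 MCA, 4 LCA).
#' @param table Class table from [ntr_class_table()].
#' @param refs Reference temperatures from [reference_temps()].
#' @return Named numeric vector following [feature_schema()].
#' @export
extract_features <- function(subject, table = ntr_class_table(),
                             refs = reference_temps()) {
  stopifnot(is.list(subject), !is.null(subject$left), !is.null(subject$right))
  left <- extract_foot(subject$left, "L", table, refs)
  right <- extract_foot(subject$right, "R", table, refs)
  etds <- mapply(etd, left$ets[c("Foot", ANGIOSOMES)], right$ets[c("Foot", ANGIOSOMES)])
  names(etds) <- paste(c("Foot", ANGIOSOMES), "ETD", sep = "_")
  out <- c(left$features, right$features, etds)
  out[feature_schema(table)]
}

#' Build a feature table from a list of subjects
#'
#' Applies [extract_features()] to each subject and assembles a feature
#' table: one row per subject, a `label` column (factor with levels
#' `healthy`, `diabetic`) and one numeric column per schema feature.
#'
#' @param subjects List of subject records, each with a `label` element.
#' @inheritParams extract_features
#' @return A data.frame feature table.
#' @export
extract_feature_table <- function(subjects, table = ntr_class_table(),
                                  refs = reference_temps()) {
  stopifnot(length(subjects) > 0)
  mat <- t(vapply(subjects, extract_features, numeric(length(feature_schema(table))),
                  table = table, refs = refs))
  labels <- vapply(subjects, function(s) as.character(s$label), character(1))
  ft <- data.frame(label = factor(labels, levels = c("healthy", "diabetic")), mat,
                   check.names = FALSE)
  rownames(ft) <- vapply(subjects, function(s) as.character(s$id), character(1))
  ft
}

#' Read and write subject records as plain text
#'
#' A subject is stored as four CSV matrices (temperature grid and integer
#' angiosome mask per foot, files `<id>_L_temps.csv`, `<id>_L_mask.csv` and
#' the `R` counterparts) plus a JSON manifest `<id>.json` holding the
#' subject id, class label and generating seed. Mask labels: 0 background,
#' 1 MPA, 2 LPA, 3 MCA, 4 LCA.
#'
#' @param subject Subject record (see [extract_features()]).
#' @param dir Directory for the files.
#' @param id Subject id; defaults to `subject$id`.
#' @return `write_subject()` returns the manifest path invisibly;
#'   `read_subject()` returns a subject record.
#' @export
write_subject <- function(subject, dir, id = subject$id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (side in c("L", "R")) {
    foot <- if (side == "L") subject$left else subject$right
    utils::write.table(foot$grid, file.path(dir, sprintf("%s_%s_temps.csv", id, side)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(foot$mask, file.path(dir, sprintf("%s_%s_mask.csv", id, side)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(id = as.character(id), label = as.character(subject$label),
                   seed = subject$seed)
  path <- file.path(dir, sprintf("%s.json", id))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subject
#' @export
read_subject <- function(dir, id) {
  manifest <- jsonlite::read_json(file.path(dir, sprintf("%s.json", id)))
  read_foot <- function(side) {
    grid <- as.matrix(utils::read.table(
      file.path(dir, sprintf("%s_%s_temps.csv", id, side)), sep = ","))
    mask <- as.matrix(utils::read.table(
      file.path(dir, sprintf("%s_%s_mask.csv", id, side)), sep = ","))
    dimnames(grid) <- NULL
    dimnames(mask) <- NULL
    storage.mode(mask) <- "integer"
    list(grid = grid, mask = mask)
  }
  list(id = manifest$id, label = manifest$label, seed = manifest$seed,
       left = read_foot("L"), right = read_foot("R"))
}
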