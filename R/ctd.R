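#' Classify turbidity anomalies into plume stages
#'
#' Plume bottle samples are staged from the turbidity anomaly above local
#' background (delta-NTU): background water below 0.01, near-plume (above or
#' below the non-buoyant layer, pending vertical context) in \[0.01, 0.02),
#' non-buoyant plume in \[0.02, 0.06\], and rising plume above 0.06. The
#' interval conventions make the categories disjoint while honouring the
#' strict field thresholds (rising takes precedence where ranges would
#' overlap).
#'
#' @param delta_ntu Numeric vector of non-negative turbidity anomalies; `NA`
#'   propagates.
#' @return Character vector over `"background"`, `"near_plume"`,
#'   `"non_buoyant_plume"`, `"rising_plume"`.
#' @examples
#' classify_turbidity(c(0.005, 0.011, 0.049, 0.49))
#' @export
classify_turbidity <- function(delta_ntu) {
  if (any(delta_ntu < 0, na.rm = TRUE)) {
    stop("invalid turbidity: delta_ntu must be non-negative", call. = FALSE)
  }
  out <- rep(NA_character_, length(delta_ntu))
  ok <- !is.na(delta_ntu)
  x <- delta_ntu[ok]
  out[ok] <- ifelse(x < 0.01, "background",
             ifelse(x < 0.02, "near_plume",
             ifelse(x <= 0.06, "non_buoyant_plume", "rising_plume")))
  out
}

#' Assign above/below-plume context within a CTD cast
#'
#' Near-plume samples (turbidity class `near_plume`) are split into
#' `above_plume` and `below_plume` relative to the depth of the laterally
#' spreading plume layer, taken as the deepest bottle with plume-level
#' turbidity (delta-NTU above the 0.02 non-buoyant threshold); when no
#' bottle reaches plume level, the bottle with maximum delta-NTU serves as
#' reference. Shallower than (or exactly at) the reference is above, deeper
#' is below. Background, non-buoyant and rising samples keep their
#' turbidity class. A single-bottle cast offers no vertical reference, so
#' its near-plume samples are left `unclassified` with an explanatory note,
#' as are casts with no turbidity data at all.
#'
#' @param depth Numeric vector of bottle depths (m) for one cast.
#' @param delta_ntu Matching turbidity anomalies (`NA` allowed).
#' @return A data.frame with columns `category` (one of `background`,
#'   `above_plume`, `below_plume`, `non_buoyant_plume`, `rising_plume`,
#'   `unclassified`) and `evidence`.
#' @examples
#' assign_vertical_context(c(2477, 2568, 2653), c(0.49, 0.011, 0.117))
#' @export
assign_vertical_context <- function(depth, delta_ntu) {
  stopifnot(length(depth) == length(delta_ntu))
  n <- length(depth)
  if (all(is.na(delta_ntu))) {
    return(data.frame(
      category = rep("unclassified", n),
      evidence = rep("no turbidity data in cast", n),
      stringsAsFactors = FALSE))
  }
  cls <- classify_turbidity(delta_ntu)
  category <- cls
  evidence <- sprintf("dNTU = %s", format(delta_ntu))
  category[is.na(cls)] <- "unclassified"
  evidence[is.na(cls)] <- "turbidity missing"

  near <- !is.na(cls) & cls == "near_plume"
  if (any(near)) {
    with_ntu <- which(!is.na(delta_ntu))
    if (length(with_ntu) < 2L) {
      category[near] <- "unclassified"
      evidence[near] <- "near-plume turbidity but single-bottle cast: no vertical reference"
    } else {
      # reference: the deepest bottle with plume-level turbidity (> 0.02),
      # i.e. the non-buoyant layer; else the turbidity maximum
      plume_level <- with_ntu[delta_ntu[with_ntu] > 0.02]
      zref <- if (length(plume_level)) max(depth[plume_level]) else
        depth[with_ntu[which.max(delta_ntu[with_ntu])]]
      above <- near & depth <= zref   # tie at the reference depth -> above
      category[near & above] <- "above_plume"
      category[near & !above] <- "below_plume"
      evidence[near] <- sprintf(
        "dNTU = %s, %s plume reference depth %g m",
        format(delta_ntu[near]),
        ifelse(depth[near] <= zref, "at/above", "below"), zref)
    }
  }
  data.frame(category = category, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Classify the bottles of one or more CTD casts
#'
#' Convenience wrapper: applies [classify_turbidity()] and
#' [assign_vertical_context()] per cast and appends `category` and
#' `evidence` columns.
#'
#' @param samples A data.frame with at least `depth` and `delta_ntu`; a
#'   `cast` column, when present, delimits casts (otherwise the whole table
#'   is treated as one cast).
#' @return `samples` with `category` and `evidence` columns appended.
#' @examples
#' classify_plume_samples(
#'   data.frame(depth = c(2477, 2568, 2653), delta_ntu = c(0.49, 0.011, 0.117)))
#' @export
classify_plume_samples <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("depth", "delta_ntu") %in% names(samples)))
  cast <- if ("cast" %in% names(samples)) samples$cast else rep(1L, nrow(samples))
  out <- samples
  out$category <- NA_character_
  out$evidence <- NA_character_
  for (cs in unique(cast)) {
    idx <- which(cast == cs)
    ctx <- assign_vertical_context(samples$depth[idx], samples$delta_ntu[idx])
    out$category[idx] <- ctx$category
    out$evidence[idx] <- ctx$evidence
  }
  out
}

#' Parse a delimited CTD bottle table
#'
#' Reads a tab-separated bottle table with a header row. The columns `name`,
#' `depth` and `delta_ntu` are mandatory; further hydrographic columns
#' (potential temperature, salinity, helium isotope anomaly, coordinates) are
#' carried through when present. Missing numeric entries (empty, `-`, or an
#' en dash) are recorded as `NA`, never as zero.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame, one row per bottle; empty input yields an empty
#'   data.frame with a warning.
#' @examples
#' parse_bottle_table(
#'   system.file("extdata", "mar_ctd_bottles.tsv", package = "hydroplume"))
#' @export
parse_bottle_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) {
    warning("empty bottle table: ", path)
    return(data.frame(name = character(), depth = numeric(),
                      delta_ntu = numeric(), stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "-", "–", "NA"),
                          check.names = FALSE)
  mandatory <- c("name", "depth", "delta_ntu")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop("bottle table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c("depth", "delta_ntu", "potential_temp", "salinity", "delta_he3",
      "latitude", "longitude", "eh"), names(df))
  df[numeric_cols] <- lapply(df[numeric_cols], function(x)
    suppressWarnings(as.numeric(x)))
  if (any(df$depth <= 0, na.rm = TRUE)) {
    stop("bottle depths must be positive", call. = FALSE)
  }
  df
}

#' Bottle summary for four Mid-Atlantic Ridge vent fields
#'
#' The packaged bottle table for the Irinovskoe, Ashadze-2, Semenov-2 and
#' Logatchev-1 hydrothermal fields (20 samples: CTD bottles plus ROV fluid
#' samples), with depth, turbidity anomaly, potential temperature, salinity,
#' helium isotope anomaly and the field-assigned sample character.
#'
#' @return A data.frame of 20 bottle records.
#' @examples
#' head(mar_bottle_table())
#' @export
mar_bottle_table <- function() {
  parse_bottle_table(
    system.file("extdata", "mar_ctd_bottles.tsv", package = "hydroplume"))
}

#' Check printed sample labels against turbidity thresholds
#'
#' Field-assigned sample labels occasionally disagree with the turbidity
#' thresholds. Labels asserting *low* plume influence carry a turbidity
#' ceiling (background: 0.01; above/below plume: 0.02), and a bottle whose
#' delta-NTU strictly exceeds its ceiling is flagged as discordant with a
#' warning. Labels asserting plume influence at low turbidity are *not*
#' flagged: such calls can legitimately rest on Eh or helium-isotope
#' evidence, which turbidity alone cannot refute.
#'
#' @param samples A data.frame with `name`, `delta_ntu` and a label column.
#' @param label_col Name of the column holding the printed label
#'   (default `"character"`).
#' @return Invisibly, a data.frame of discordant rows (possibly empty) with
#'   columns `name`, `label`, `delta_ntu`, `ceiling`; one warning is issued
#'   per discordance.
#' @examples
#' suppressWarnings(check_label_discordance(mar_bottle_table()))
#' @export
check_label_discordance <- function(samples, label_col = "character") {
  stopifnot(is.data.frame(samples),
            all(c("name", "delta_ntu", label_col) %in% names(samples)))
  lab <- tolower(samples[[label_col]])
  ceiling_of <- ifelse(grepl("backgr", lab), 0.01,
                ifelse(grepl("(above|below).*plume", lab), 0.02, NA_real_))
  bad <- !is.na(ceiling_of) & !is.na(samples$delta_ntu) &
    samples$delta_ntu > ceiling_of
  out <- data.frame(name = samples$name[bad],
                    label = samples[[label_col]][bad],
                    delta_ntu = samples$delta_ntu[bad],
                    ceiling = ceiling_of[bad],
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    warning(sprintf(
      "label discordance: %s is labelled '%s' but dNTU = %g exceeds %g",
      out$name[i], out$label[i], out$delta_ntu[i], out$ceiling[i]),
      call. = FALSE)
  }
  invisible(out)
}
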