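#' Endocranial volume from brain mass
#'
#' Converts brain mass to endocranial volume using a brain tissue density of
#' 1.036 g per cubic centimetre, for species where ECV was not reported
#' directly.
#'
#' @param brain_mass brain mass in grams (vectorized; NA passed through).
#' @return endocranial volume in cm^3.
#' @export
ecv_from_brain_mass <- function(brain_mass) {
  if (any(brain_mass <= 0, na.rm = TRUE)) {
    stop("brain mass must be positive", call. = FALSE)
  }
  brain_mass / 1.036
}

BRAIN_DENSITY_G_PER_CM3 <- 1.036
CORTEX_NEURON_COEF <- 37813551.018
CORTEX_NEURON_EXP <- 0.891
CEREBELLUM_NEURON_COEF <- 69640042.656
CEREBELLUM_NEURON_EXP <- 0.936

#' Allometric cortical neuron count for primates
#'
#' Predicts the number of cortical neurons from brain mass by the primate
#' scaling rule 37,813,551.018 * brain_mass^0.891. Intended only for primate
#' species with no measured count: if a measured value is supplied, the
#' function refuses rather than overwrite it (measured data always win).
#'
#' @param brain_mass brain mass in grams (vectorized).
#' @param measured optional vector of measured counts; any non-NA entry
#'   triggers an error.
#' @return predicted neuron counts.
#' @export
primate_cortex_neurons <- function(brain_mass, measured = NULL) {
  allometric_neurons(brain_mass, CORTEX_NEURON_COEF, CORTEX_NEURON_EXP, measured)
}

#' Allometric cerebellar neuron count for primates
#'
#' As \code{\link{primate_cortex_neurons}} but with the cerebellar scaling
#' rule 69,640,042.656 * brain_mass^0.936.
#'
#' @inheritParams primate_cortex_neurons
#' @return predicted neuron counts.
#' @export
primate_cerebellum_neurons <- function(brain_mass, measured = NULL) {
  allometric_neurons(brain_mass, CEREBELLUM_NEURON_COEF, CEREBELLUM_NEURON_EXP, measured)
}

allometric_neurons <- function(brain_mass, coef, exponent, measured) {
  if (any(!is.finite(brain_mass) | brain_mass <= 0, na.rm = FALSE)) {
    stop("brain mass must be positive and finite", call. = FALSE)
  }
  if (!is.null(measured) && any(!is.na(measured))) {
    stop("measured neuron counts present; refusing to impute over them", call. = FALSE)
  }
  coef * brain_mass^exponent
}

#' Fill missing neuron counts in a predictor table by primate allometry
#'
#' Applies the primate scaling rules to fill NA entries of
#' \code{cortex_neurons} or \code{cerebellum_neurons} for primate species
#' with known brain mass. Measured values are never overwritten, so the
#' operation is idempotent. Neuronal *density* is deliberately not imputable:
#' density and number are decoupled in primates (more neurons does not mean
#' lower density), so no scaling rule applies and asking for one is an
#' error.
#'
#' @param table predictor data frame with a \code{species} column.
#' @param brain_mass named vector (by species) of brain masses in grams.
#' @param is_primate named logical vector (by species).
#' @param column which count column to fill: \code{"cortex_neurons"} or
#'   \code{"cerebellum_neurons"}. Density columns raise an error.
#' @return the table with NA counts filled where possible, plus a
#'   \code{"provenance"} attribute marking each filled cell
#'   \code{"scaled_from_brain_mass"}.
#' @export
impute_neuron_counts <- function(table, brain_mass, is_primate,
                                 column = c("cortex_neurons", "cerebellum_neurons")) {
  column <- match.arg(column, c("cortex_neurons", "cerebellum_neurons",
                                "cortex_neuron_density", "cerebellum_neuron_density"))
  if (grepl("density", column)) {
    stop("neuronal density cannot be imputed from brain mass: density and ",
         "number are decoupled in primates", call. = FALSE)
  }
  stopifnot("species" %in% names(table), column %in% names(table))
  coef <- if (column == "cortex_neurons") CORTEX_NEURON_COEF else CEREBELLUM_NEURON_COEF
  expo <- if (column == "cortex_neurons") CORTEX_NEURON_EXP else CEREBELLUM_NEURON_EXP
  prov <- attr(table, "provenance")
  if (is.null(prov)) prov <- list()
  fillable <- is.na(table[[column]]) &
    table$species %in% names(brain_mass)[!is.na(brain_mass)] &
    table$species %in% names(is_primate)[is_primate %in% TRUE]
  if (any(fillable)) {
    sp <- table$species[fillable]
    table[[column]][fillable] <- allometric_neurons(brain_mass[sp], coef, expo, NULL)
    prov[[column]] <- stats::setNames(rep("scaled_from_brain_mass", length(sp)), sp)
  }
  attr(table, "provenance") <- prov
  table
}

#' Reverse a cognition score so that high means good
#'
#' Some published composite cognition scores are coded with high values
#' indicating poor performance; this negates them so the ranking is exactly
#' inverted and a high score indicates good performance.
#'
#' @param raw numeric score vector (NA allowed).
#' @return the negated scores.
#' @export
reverse_cognition_score <- function(raw) {
  if (!length(raw)) stop("empty score vector", call. = FALSE)
  -raw
}

# predictor columns that are log-transformed before modelling
LOG_COLUMNS <-c("ecv", "group_size", "home_range", "day_journey",
                 "cortex_neurons", "cerebellum_neurons",
                 "cortex_neuron_density", "cerebellum_neuron_density")

#' Apply the standard predictor transforms
#'
#' Natural-log-transforms the size-like predictor columns (ECV, group size,
#' home range, day journey, cortical and cerebellar neuron numbers and
#' densities) where present; percentage fruit in diet, self-control and
#' general cognition scores are left untouched. If a tree (or
#' \code{species_cov}) and a \code{body_mass} column are available, residual
#' brain volume (\code{rbv}) is added afterwards: the residuals of a
#' phylogenetic GLS regression of log ECV on log body mass (species with
#' either value missing get NA).
#'
#' @param table predictor data frame with a \code{species} column.
#' @param cov optional \code{species_cov} covering at least the species with
#'   both ECV and body mass, used for the RBV regression.
#' @return the transformed table, with attribute \code{"log_columns"} naming
#'   the columns that were logged.
#' @export
apply_transforms <- function(table, cov = NULL) {
  stopifnot(is.data.frame(table), "species" %in% names(table))
  present <- intersect(LOG_COLUMNS, names(table))
  for (col in present) {
    bad <- !is.na(table[[col]]) & table[[col]] <= 0
    if (any(bad)) {
      stop(sprintf("non-positive value in log column '%s' for species: %s",
                   col, paste(table$species[bad], collapse = ", ")), call. = FALSE)
    }
    table[[col]] <- log(table[[col]])
  }
  attr(table, "log_columns") <- present
  if (!is.null(cov) && all(c("ecv", "body_mass") %in% names(table))) {
    ok <- !is.na(table$ecv) & !is.na(table$body_mass) & table$species %in% cov$labels
    rbv <- rep(NA_real_, nrow(table))
    if (sum(ok) >= 3) {
      sub <- tree_subset_cov(cov, table$species[ok])
      rbv[ok] <- pgls_residuals(table$ecv[ok], log(table$body_mass[ok]), sub)
    }
    table$rbv <- rbv
  }
  table
}

# restrict a species_cov to a subset of its labels (keeps unit diagonal)
tree_subset_cov <- function(cov, labels) {
  stopifnot(all(labels %in% cov$labels))
  structure(list(labels = labels, V = cov$V[labels, labels, drop = FALSE],
                 M = NULL, lambda = NULL), class = "species_cov")
}

#' Write a predictor table with a sidecar metadata file
#'
#' Writes the table as CSV plus a JSON sidecar (same path with
#' \code{.json} appended) recording measurement units, which columns have
#' been log-transformed, and per-cell imputation provenance
#' (\code{measured}, \code{scaled_from_brain_mass} or \code{missing}).
#' \code{\link{read_predictor_table}} restores the table with its
#' attributes.
#'
#' @param table predictor data frame (attributes \code{log_columns} and
#'   \code{provenance} are honoured if present).
#' @param path CSV path.
#' @param units optional named list/vector of unit strings per column.
#' @return \code{path}, invisibly.
#' @export
write_predictor_table <- function(table, path, units = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  prov <- attr(table, "provenance")
  value_cols <- setdiff(names(table), "species")
  provenance <- lapply(stats::setNames(value_cols, value_cols), function(col) {
    out <- ifelse(is.na(table[[col]]), "missing", "measured")
    if (!is.null(prov[[col]])) {
      hit <- match(names(prov[[col]]), table$species)
      out[hit[!is.na(hit)]] <- unname(prov[[col]][!is.na(hit)])
    }
    as.list(stats::setNames(out, table$species))
  })
  meta <- list(units = as.list(units),
               log_columns = as.list(attr(table, "log_columns")),
               provenance = provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a predictor table written by \code{write_predictor_table}
#'
#' @param path CSV path; the \code{.json} sidecar is read when present.
#' @return the data frame with \code{log_columns}, \code{provenance} and
#'   \code{units} attributes restored.
#' @export
read_predictor_table <- function(path) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(table, "log_columns") <- unlist(meta$log_columns)
    attr(table, "units") <- meta$units
    attr(table, "provenance") <- lapply(meta$provenance, unlist)
  }
  table
}
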