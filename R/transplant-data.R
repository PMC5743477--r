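#' Construct a transplant dataset
#'
#' A `transplant_dataset` holds one row per measured plant from a reciprocal
#' transplant experiment: the species, the garden (planting site region), the
#' ecotype (seed origin region), a replicate label, and aboveground dry
#' biomass in grams. Biomass is `NA` for plants that died before harvest;
#' such rows are retained in the dataset but excluded from every model fit.
#'
#' Garden and ecotype identifiers are opaque, case-sensitive strings drawn
#' from a shared region vocabulary. A plant is *sympatric* (local) when its
#' ecotype equals its garden region, *allopatric* otherwise.
#'
#' @param records data.frame with columns `species`, `garden`, `ecotype`,
#'   `replicate`, `biomass`. `biomass` must be numeric; non-positive values
#'   are treated as missing (a dead or unmeasurable plant).
#' @param regions optional character vector fixing the region vocabulary and
#'   its order; defaults to the union of garden and ecotype values in order
#'   of first appearance.
#' @return An object of class `transplant_dataset`: a list with elements
#'   `records` (data.frame), `regions` (character) and `species_regions`
#'   (named list mapping species to the regions with available ecotypes).
#' @export
transplant_dataset <- function(records, regions = NULL) {
  required <- c("species", "garden", "ecotype", "replicate", "biomass")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[required]
  records$species <- as.character(records$species)
  records$garden <- as.character(records$garden)
  records$ecotype <- as.character(records$ecotype)
  if (!is.numeric(records$biomass)) {
    stop("biomass must be numeric (use NA for missing)")
  }
  bad <- is.finite(records$biomass) & records$biomass <= 0
  records$biomass[bad] <- NA_real_
  records$biomass[!is.finite(records$biomass)] <- NA_real_

  seen <- unique(c(records$garden, records$ecotype))
  if (is.null(regions)) {
    regions <- seen
  } else {
    regions <- as.character(regions)
    unknown <- setdiff(seen, regions)
    if (length(unknown) > 0L) {
      stop("records use region(s) outside the supplied vocabulary: ",
           paste(unknown, collapse = ", "))
    }
  }
  species_regions <- lapply(
    split(records$ecotype, records$species),
    function(e) regions[regions %in% e]
  )
  bad_garden <- !(records$garden %in% regions)
  if (any(bad_garden)) {
    stop("garden value outside region vocabulary in row ", which(bad_garden)[1L])
  }
  rownames(records) <- NULL
  structure(
    list(records = records, regions = regions, species_regions = species_regions),
    class = "transplant_dataset"
  )
}

#' @export
print.transplant_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$records$biomass))
  cat("Reciprocal transplant dataset\n")
  cat("  ", nrow(x$records), " plants (", n_miss, " missing biomass), ",
      length(unique(x$records$species)), " species, ",
      length(x$regions), " regions [", paste(x$regions, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Read a transplant dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `species`,
#' `garden`, `ecotype`, `replicate`, `biomass` (missing biomass written as
#' `NA` or left empty). `column_map` renames nonstandard headers, e.g.
#' `c(biomass = "dry_mass_g")` reads column `dry_mass_g` as biomass.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping standard names
#'   to the file's column names.
#' @return A [transplant_dataset].
#' @export
read_dataset <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  required <- c("species", "garden", "ecotype", "replicate", "biomass")
  for (std in names(column_map)) {
    src <- column_map[[std]]
    if (!src %in% names(raw)) {
      stop("column_map names absent column '", src, "'")
    }
    names(raw)[names(raw) == src] <- std
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bm <- suppressWarnings(as.numeric(raw$biomass))
  bad <- which(!is.na(raw$biomass) & is.na(bm))
  if (length(bad) > 0L) {
    stop("non-numeric biomass value '", raw$biomass[bad[1L]],
         "' in data row ", bad[1L])
  }
  raw$biomass <- bm
  raw$replicate <- suppressWarnings(as.integer(raw$replicate))
  transplant_dataset(raw)
}

#' Write a transplant dataset to CSV
#'
#' Inverse of [read_dataset()]: writes the record table with the standard
#' header, `NA` for missing biomass, full precision.
#'
#' @param ds a [transplant_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "transplant_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}

#' Restrict a dataset to a full reciprocal design
#'
#' Keeps, for every species, only the ecotypes originating from the supplied
#' garden regions and only the gardens for which that species has a local
#' ecotype. After the restriction every retained species x garden cell
#' contains its local ecotype, so sympatric/allopatric contrasts are defined
#' everywhere. Species missing some garden regions lose both the foreign
#' ecotypes and the gardens without a local ecotype. The operation is
#' idempotent.
#'
#' @param ds a [transplant_dataset].
#' @param garden_regions character vector of regions that host a garden;
#'   defaults to the set of garden values present in the data.
#' @return A restricted [transplant_dataset].
#' @export
simplify_to_full_reciprocal <- function(ds, garden_regions = NULL) {
  stopifnot(inherits(ds, "transplant_dataset"))
  if (is.null(garden_regions)) garden_regions <- unique(ds$records$garden)
  if (!all(garden_regions %in% ds$regions)) {
    stop("garden_regions must be a subset of the dataset's region vocabulary")
  }
  rec <- ds$records
  keep <- logical(nrow(rec))
  for (sp in names(ds$species_regions)) {
    allowed <- intersect(ds$species_regions[[sp]], garden_regions)
    if (length(allowed) < 2L) {
      stop("species '", sp, "' has fewer than 2 regions after restriction; ",
           "no sympatric/allopatric contrast is possible")
    }
    idx <- rec$species == sp
    keep[idx] <- rec$ecotype[idx] %in% allowed & rec$garden[idx] %in% allowed
  }
  out <- transplant_dataset(rec[keep, , drop = FALSE],
                            regions = ds$regions[ds$regions %in% garden_regions])
  out
}

#' Summarize the experimental design of a dataset
#'
#' @param ds a [transplant_dataset].
#' @return An object of class `design_summary`: number of species, gardens,
#'   species x garden cells, plants with measured biomass, and a per-cell
#'   table of replicate counts per ecotype.
#' @export
summarize_design <- function(ds) {
  stopifnot(inherits(ds, "transplant_dataset"))
  rec <- ds$records
  cells <- unique(rec[, c("species", "garden")])
  per_cell <- as.data.frame(
    table(species = rec$species, garden = rec$garden, ecotype = rec$ecotype),
    stringsAsFactors = FALSE
  )
  per_cell <- per_cell[per_cell$Freq > 0L, , drop = FALSE]
  names(per_cell)[names(per_cell) == "Freq"] <- "n_replicates"
  rownames(per_cell) <- NULL
  structure(
    list(
      n_species = length(unique(rec$species)),
      n_gardens = length(unique(rec$garden)),
      n_cells = nrow(cells),
      n_plants = sum(!is.na(rec$biomass)),
      n_records = nrow(rec),
      per_cell_counts = per_cell
    ),
    class = "design_summary"
  )
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Design: ", x$n_species, " species, ", x$n_gardens, " gardens, ",
      x$n_cells, " species x garden cells, ", x$n_plants,
      " measured plants (of ", x$n_records, " records)\n", sep = "")
  invisible(x)
}

# rows of a dataset with measured biomass, plus the sympatry indicator
complete_records <- function(ds) {
  rec <- ds$records[!is.na(ds$records$biomass), , drop = FALSE]
  rec$sympatric <- as.integer(rec$ecotype == rec$garden)
  rownames(rec) <- NULL
  rec
}
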