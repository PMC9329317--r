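#' Column conventions for body-segment tables
#'
#' Linear measures (consistent length unit): gleno-acetabular distance `GA`,
#' femur `FL`, shank `SL`, metatarsal `MtL`, pes `PL`, humerus `HL`, forearm
#' `FaL`, metacarpal `McL`, manus `ML`. Segment skeletal hull volumes
#' (unit^3): skull, neck, trunk, tail, humerus, forearm, metacarpal, manus,
#' femur, shank, metatarsal, pes.
#' @name segmentColumns
#' @keywords internal
NULL

.linearCols <- c("GA", "FL", "SL", "MtL", "PL", "HL", "FaL", "McL", "ML")
.volumeCols <- c("skull", "neck", "trunk", "tail", "humerus", "forearm",
                 "metacarpal", "manus", "femur", "shank", "metatarsal", "pes")
.forelimbCols <- c("HL", "FaL", "McL", "ML")
.hindlimbCols <- c("FL", "SL", "MtL", "PL")

#' Assemble a per-taxon body-segment table
#'
#' Joins linear measures and segment hull volumes by taxon, derives the
#' whole-body convex hull volume (WBCHV) as the sum of the available segment
#' volumes, and the limb lengths as sums of their four segments
#' (forelimb = HL+FaL+McL+ML, hindlimb = FL+SL+MtL+PL). Taxa with missing
#' segment volumes (incomplete fossils) get WBCHV over the available segments
#' and `complete = FALSE`, which downstream analyses can filter on.
#'
#' @param linear data.frame with column `taxon` plus (a subset of) the nine
#'   linear measures
#' @param volumes data.frame with column `taxon` plus (a subset of) the twelve
#'   segment volumes
#' @return a `segmentTable` data.frame with derived columns `WBCHV`,
#'   `forelimb_length`, `hindlimb_length`, `complete`
#' @export
assembleSegmentTable <- function(linear, volumes) {
  if (!"taxon" %in% names(linear) || !"taxon" %in% names(volumes)) {
    stop("both inputs need a 'taxon' column")
  }
  taxa <- intersect(linear$taxon, volumes$taxon)
  if (!length(taxa)) stop("no overlapping taxa between linear and volume tables")
  lin <- linear[match(taxa, linear$taxon), intersect(.linearCols, names(linear)), drop = FALSE]
  vol <- volumes[match(taxa, volumes$taxon), intersect(.volumeCols, names(volumes)), drop = FALSE]
  for (d in list(lin, vol)) {
    bad <- vapply(d, function(v) any(!is.na(v) & v <= 0), logical(1))
    if (any(bad)) {
      stop("non-positive measurement in column(s): ",
           paste(names(d)[bad], collapse = ", "))
    }
  }
  vm <- as.matrix(vol)
  out <- data.frame(taxon = taxa, lin, vol,
                    WBCHV = rowSums(vm, na.rm = TRUE),
                    complete = !apply(is.na(vm), 1, any),
                    stringsAsFactors = FALSE)
  if (all(.forelimbCols %in% names(lin))) {
    out$forelimb_length <- rowSums(as.matrix(lin[, .forelimbCols]))
  }
  if (all(.hindlimbCols %in% names(lin))) {
    out$hindlimb_length <- rowSums(as.matrix(lin[, .hindlimbCols]))
  }
  structure(out, class = c("segmentTable", "data.frame"), normalised = FALSE)
}

#' Size-normalise a segment table by WBCHV
#'
#' Linear metrics (including limb-length sums) are divided by WBCHV^(1/3),
#' volumetric metrics by WBCHV, removing isometric size so residual variation
#' is shape. The normalised `trunk` column is the "normalised torso volume"
#' used by the regime models. The raw `WBCHV` column is retained for
#' reference. Normalisation is shape-idempotent: a globally rescaled animal
#' (lengths x s, volumes x s^3) yields identical normalised values.
#'
#' @param table a `segmentTable` from [assembleSegmentTable()]
#' @param exponent exponent applied to WBCHV for linear metrics (default 1/3)
#' @return the normalised `segmentTable` (attribute `normalised = TRUE`)
#' @export
sizeNormalise <- function(table, exponent = 1 / 3) {
  if (isTRUE(attr(table, "normalised"))) return(table)
  if (any(!is.finite(table$WBCHV)) || any(table$WBCHV <= 0)) {
    stop("WBCHV must be > 0 for every taxon")
  }
  out <- table
  lin <- intersect(c(.linearCols, "forelimb_length", "hindlimb_length"), names(table))
  vol <- intersect(.volumeCols, names(table))
  for (cn in lin) out[[cn]] <- table[[cn]] / table$WBCHV^exponent
  for (cn in vol) out[[cn]] <- table[[cn]] / table$WBCHV
  attr(out, "normalised") <- TRUE
  out
}

#' Coefficient of variation by group
#'
#' CoV = sample standard deviation (n - 1 denominator) / mean, computed for
#' one metric within each group. Used to compare the tightness of
#' size-normalised segment proportions across ecological categories.
#'
#' @param values named numeric vector (one value per taxon)
#' @param groups group labels aligned with `values` (by name when both are
#'   named, else by position)
#' @param metric metric name recorded in the output
#' @return data.frame of class `covProfile` with columns group, metric, n, cov
#' @export
groupCoV <- function(values, groups, metric = deparse(substitute(values))) {
  if (!is.null(names(values)) && !is.null(names(groups))) {
    groups <- groups[names(values)]
  }
  if (length(values) != length(groups)) stop("values and groups lengths differ")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  res <- lapply(split(values, groups), function(v) {
    if (length(v) < 2) stop("CoV needs at least 2 taxa per group")
    m <- mean(v)
    if (m <= 0) stop("CoV undefined: group mean <= 0")
    c(n = length(v), cov = sd(v) / m)
  })
  out <- data.frame(group = names(res), metric = metric,
                    n = vapply(res, `[[`, 0, "n"),
                    cov = vapply(res, `[[`, 0, "cov"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("covProfile", "data.frame"))
}

#' Read / write segment tables as CSV
#'
#' The CSV schema mirrors the linear-measure abbreviations (GA, FL, SL, MtL,
#' PL, HL, FaL, McL, ML) and segment-volume names documented in
#' [assembleSegmentTable()].
#'
#' @param file path to CSV
#' @return a `segmentTable`
#' @export
readSegmentTable <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(d)) stop("segment CSV needs a 'taxon' column")
  lin <- d[, c("taxon", intersect(.linearCols, names(d))), drop = FALSE]
  vol <- d[, c("taxon", intersect(.volumeCols, names(d))), drop = FALSE]
  assembleSegmentTable(lin, vol)
}

#' @rdname readSegmentTable
#' @param table a `segmentTable`
#' @export
writeSegmentTable <- function(table, file) {
  write.csv(as.data.frame(table), file = file, row.names = FALSE)
}
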