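#' Construct a region atlas
#'
#' A region atlas assigns every source-localized region to exactly one
#' functional network and a hemisphere. Row order defines the region index
#' order used by all epoch/rest tensors in the package.
#'
#' @param region_id Character vector of unique region identifiers.
#' @param network Character vector of functional network labels (e.g. the 11
#'   networks of a whole-brain functional parcellation: Motor, Visual,
#'   Auditory, DAN, FPN, CON, ...).
#' @param hemisphere Character vector; each entry one of `"left"`, `"right"`,
#'   `"midline"`.
#' @param x,y,z Optional numeric coordinates in millimeters (metadata only).
#'
#' @return A tibble of class `region_atlas` with one row per region.
#' @export
#' @examples
#' region_atlas(
#'   region_id = c("M1L", "V1R"),
#'   network = c("Motor", "Visual"),
#'   hemisphere = c("left", "right")
#' )
region_atlas <- function(region_id, network, hemisphere, x = NULL, y = NULL,
                         z = NULL) {
  region_id <- as.character(region_id)
  network <- as.character(network)
  hemisphere <- as.character(hemisphere)
  n <- length(region_id)
  if (length(network) != n || length(hemisphere) != n) {
    stop("region_id, network and hemisphere must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(region_id)) {
    stop("duplicate region_id: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_hemi <- setdiff(unique(hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi)) {
    stop("unknown hemisphere value(s): ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(network) || any(!nzchar(network))) {
    stop("every region must carry a non-empty network label", call. = FALSE)
  }
  out <- tibble::tibble(region_id = region_id, network = network,
                        hemisphere = hemisphere)
  if (!is.null(x)) out$x <- as.numeric(x)
  if (!is.null(y)) out$y <- as.numeric(y)
  if (!is.null(z)) out$z <- as.numeric(z)
  class(out) <- c("region_atlas", class(out))
  out
}

#' Read a region table from a TSV file
#'
#' Expects a tab-separated file with header columns `region_id`, `network`,
#' `hemisphere` and optional `x`, `y`, `z` coordinate columns.
#'
#' @param path Path to the TSV file.
#' @return A [region_atlas] tibble; row order defines region index order.
#' @export
read_region_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("region_id", "network", "hemisphere")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("region table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  region_atlas(
    region_id = tab$region_id, network = tab$network,
    hemisphere = tab$hemisphere,
    x = if ("x" %in% names(tab)) tab$x,
    y = if ("y" %in% names(tab)) tab$y,
    z = if ("z" %in% names(tab)) tab$z
  )
}

#' Write a region atlas to a TSV file
#'
#' @param atlas A [region_atlas].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  readr::write_tsv(tibble::as_tibble(atlas), path, progress = FALSE)
  invisible(path)
}

#' Region indices belonging to a network
#'
#' @param atlas A [region_atlas].
#' @param network Network name.
#' @return Integer vector of row indices into the atlas (= tensor region
#'   indices).
#' @export
network_regions <- function(atlas, network) {
  idx <- which(atlas$network == network)
  if (!length(idx)) {
    stop("network '", network, "' has no regions in the atlas", call. = FALSE)
  }
  idx
}
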