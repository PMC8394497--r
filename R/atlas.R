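#' Region atlas with contralateral pairing
#'
#' Holds the label book-keeping used throughout: every nonzero label has a
#' name and belongs either to exactly one mirrored left/right pair or to the
#' unpaired (midline) set. The full-scale human atlas this emulates has 40
#' contralateral pairs plus 3 unpaired midline structures (brainstem, corpus
#' callosum, third ventricle), i.e. 83 regions.
#'
#' @param regions data.frame with columns \code{label}, \code{name},
#'   \code{hemi} ("L", "R" or "M").
#' @param pairs data.frame with columns \code{pair} (index), \code{name},
#'   \code{left}, \code{right} (labels).
#' @param unpaired integer vector of midline labels.
#' @return An object of class \code{region_atlas}.
#' @export
region_atlas <- function(regions, pairs, unpaired) {
  stopifnot(is.data.frame(regions), is.data.frame(pairs))
  paired <- c(pairs$left, pairs$right)
  all_lab <- sort(c(paired, unpaired))
  if (any(duplicated(all_lab)))
    stop("a label appears in more than one pair/unpaired slot")
  if (!setequal(all_lab, regions$label))
    stop("pairs + unpaired must cover exactly the atlas labels")
  structure(list(regions = regions, pairs = pairs,
                 unpaired = as.integer(unpaired)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas: %d regions (%d contralateral pairs + %d unpaired)\n",
              nrow(x$regions), nrow(x$pairs), length(x$unpaired)))
  invisible(x)
}

#' Number of regions in an atlas
#' @param atlas a \code{region_atlas}.
#' @return Integer region count (2 * pairs + unpaired).
#' @export
n_regions <- function(atlas) nrow(atlas$regions)
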