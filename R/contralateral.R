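#' Fold per-region features into contralateral mean / absolute difference
#'
#' For every contralateral pair and every signal/texture feature f, derives
#' the pair mean \eqn{(f_L + f_R)/2} and the absolute difference
#' \eqn{|f_L - f_R|}. Volumes are not folded: they pass through unfolded,
#' one column per region. With the full 40-pair atlas and the default
#' 37 signal+texture features this yields 37 x 2 x 40 = 2960 derived
#' columns plus 83 volume columns. If either member of a pair is missing
#' (too few valid voxels) both derived features of that pair are NA.
#'
#' Column naming is deterministic: \code{<pair>.<feature>.mean},
#' \code{<pair>.<feature>.absdiff}, \code{<region>.volume}.
#'
#' @param features region x feature matrix from \code{\link{extract_all}}.
#' @param atlas a \code{\link{region_atlas}}.
#' @return Named numeric vector (one subject's row of the feature table).
#' @export
fold_contralateral <- function(features, atlas) {
  fn <- colnames(features)
  st <- setdiff(fn, "volume")
  out <- c()
  for (k in seq_len(nrow(atlas$pairs))) {
    p <- atlas$pairs[k, ]
    lrow <- features[match(p$left, atlas$regions$label), st]
    rrow <- features[match(p$right, atlas$regions$label), st]
    m <- (lrow + rrow) / 2
    a <- abs(lrow - rrow)
    names(m) <- paste0(p$name, ".", st, ".mean")
    names(a) <- paste0(p$name, ".", st, ".absdiff")
    out <- c(out, m, a)
  }
  if ("volume" %in% fn) {
    v <- features[, "volume"]
    names(v) <- paste0(atlas$regions$name, ".volume")
    out <- c(out, v)
  }
  out
}

#' Manifest of every derived column
#'
#' One row per column the folded table will contain, with its family
#' (\code{signal}, \code{texture}, \code{volume}), region or pair name and
#' mode (\code{mean}, \code{absdiff} or \code{region} for volumes), in the
#' exact column order produced by \code{\link{fold_contralateral}}.
#'
#' @param atlas a \code{\link{region_atlas}}.
#' @param registry a \code{\link{feature_registry}} data.frame.
#' @param modes which derived modes to include.
#' @return data.frame with columns \code{column}, \code{feature},
#'   \code{family}, \code{region}, \code{mode}.
#' @export
build_manifest <- function(atlas, registry = feature_registry(),
                           modes = c("mean", "absdiff")) {
  st <- registry[registry$family %in% c("signal", "texture"), ]
  rows <- list()
  for (k in seq_len(nrow(atlas$pairs))) {
    p <- atlas$pairs[k, ]
    for (mode in c("mean", "absdiff")) {
      if (!mode %in% modes) next
      rows[[length(rows) + 1L]] <- data.frame(
        column = paste0(p$name, ".", st$name, ".", mode),
        feature = st$name, family = st$family,
        region = p$name, mode = mode)
    }
  }
  if ("volume" %in% registry$name) {
    rows[[length(rows) + 1L]] <- data.frame(
      column = paste0(atlas$regions$name, ".volume"),
      feature = "volume", family = "volume",
      region = atlas$regions$name, mode = "region")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the analysis-ready subjects-by-features table
#'
#' Binds each subject's folded imaging row to the cohort table's
#' neuropsychological scores and group labels, and attaches the manifest
#' (imaging columns plus one \code{neuropsych}-family row per score).
#'
#' @param imaging_rows named list (by subject id) of
#'   \code{\link{fold_contralateral}} vectors, all with identical names.
#' @param cohort cohort data.frame (columns \code{subject_id},
#'   \code{group}, neuropsych scores).
#' @param atlas,registry used to build the manifest.
#' @param neuropsych_scores names of the cohort's score columns.
#' @return An object of class \code{feature_table}: a data.frame with
#'   \code{subject_id}, \code{group}, then feature columns; attribute
#'   \code{manifest}.
#' @export
build_feature_table <- function(imaging_rows, cohort,
                                atlas, registry = feature_registry(),
                                neuropsych_scores = c("MMSE", "BNT", "GDS",
                                                      "ADAS11", "ADNI_EF",
                                                      "ADNI_VS", "ADNI_LAN",
                                                      "ADNI_MEM")) {
  stopifnot(all(cohort$subject_id %in% names(imaging_rows)))
  img <- do.call(rbind, imaging_rows[cohort$subject_id])
  manifest <- build_manifest(atlas, registry)
  stopifnot(identical(colnames(img), manifest$column))
  np <- cohort[, intersect(neuropsych_scores, colnames(cohort)),
               drop = FALSE]
  manifest <- rbind(manifest,
                    data.frame(column = colnames(np),
                               feature = colnames(np),
                               family = "neuropsych",
                               region = NA, mode = "score"))
  tab <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                    img, np, check.names = FALSE)
  rownames(tab) <- NULL
  structure(tab, manifest = manifest, class = c("feature_table",
                                                "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("feature_table: %d subjects x %d feature columns (%s)\n",
              nrow(x), nrow(man),
              paste(sprintf("%d %s", table(man$family),
                            names(table(man$family))), collapse = ", ")))
  invisible(x)
}

#' Column manifest of a feature table
#' @param table a \code{feature_table}.
#' @return The manifest data.frame (see \code{\link{build_manifest}}).
#' @export
table_manifest <- function(table) attr(table, "manifest")
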