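# Functional-ROI selection, condition-response extraction, lateralization,
# and dummy-coded model-table construction over voxel-level inputs.

#' Voxel map
#'
#' Per-voxel localizer statistics and condition responses within one mask.
#'
#' @param voxel_id integer/character voxel identifiers.
#' @param localizer_stat numeric localizer contrast statistic per voxel.
#' @param condition_responses data frame / matrix of per-condition percent
#'   signal change, one row per voxel.
#' @param mask_label label for the mask/parcel.
#' @return An object of class `voxel_map`.
#' @export
voxel_map <- function(voxel_id, localizer_stat, condition_responses,
                      mask_label = NA_character_) {
  condition_responses <- as.data.frame(condition_responses)
  n <- length(voxel_id)
  if (n == 0L) stop("empty mask: voxel map must contain at least one voxel")
  if (length(localizer_stat) != n || nrow(condition_responses) != n) {
    stop("voxel_id, localizer_stat and condition_responses must be",
         " index-aligned")
  }
  structure(
    list(voxel_id = voxel_id, localizer_stat = as.numeric(localizer_stat),
         condition_responses = condition_responses, mask_label = mask_label),
    class = "voxel_map"
  )
}

#' @export
print.voxel_map <- function(x, ...) {
  cat("<voxel_map ", x$mask_label, "> ", length(x$voxel_id), " voxels, ",
      ncol(x$condition_responses), " conditions\n", sep = "")
  invisible(x)
}

#' Select the functional ROI: top fraction of localizer-responsive voxels
#'
#' Selects the `ceiling(fraction * mask size)` voxels with the highest
#' localizer statistic (default fraction 0.10). Ties are broken by voxel
#' id, so the selection is deterministic.
#'
#' @param m a `voxel_map`.
#' @param fraction proportion of mask voxels to select, in (0, 1].
#' @return Integer indices (into the map) of the selected voxels.
#' @export
select_froi <- function(m, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(m$voxel_id)
  k <- ceiling(fraction * n)
  ord <- order(-m$localizer_stat, m$voxel_id)
  sort(ord[seq_len(k)])
}

#' Mean condition responses over selected voxels
#'
#' @param m a `voxel_map`.
#' @param selected indices from [select_froi()].
#' @param participant,roi_label metadata carried on the result.
#' @return A `froi_response`: list with `participant`, `roi_label`,
#'   `response` (named numeric, per-condition mean percent signal change),
#'   and `n_voxels_selected`.
#' @export
extract_condition_responses <- function(m, selected,
                                        participant = NA_character_,
                                        roi_label = NULL) {
  if (length(selected) == 0L) stop("empty voxel selection")
  if (any(selected < 1L | selected > length(m$voxel_id))) {
    stop("selection outside the mask")
  }
  resp <- colMeans(m$condition_responses[selected, , drop = FALSE])
  structure(
    list(participant = participant,
         roi_label = roi_label %||% m$mask_label,
         response = resp, n_voxels_selected = length(selected)),
    class = "froi_response"
  )
}

#' @export
print.froi_response <- function(x, ...) {
  cat("<froi_response ", x$participant, "/", x$roi_label, "> ",
      x$n_voxels_selected, " voxels\n", sep = "")
  print(round(x$response, 3))
  invisible(x)
}

#' Hemispheric lateralization index
#'
#' `(LH - RH) / (LH + RH)` over counts of significant voxels per
#' hemisphere; values of `-0.25` or below are classified right-lateralized.
#'
#' @param lh_count,rh_count significant voxel counts (left, right).
#' @param threshold classification cutoff (default -0.25).
#' @return List with `index` in `[-1, 1]` and `right_lateralized` logical.
#' @export
lateralization_index <- function(lh_count, rh_count, threshold = -0.25) {
  if (lh_count + rh_count <= 0) {
    stop("lateralization undefined: no significant voxels in either",
         " hemisphere")
  }
  idx <- (lh_count - rh_count) / (lh_count + rh_count)
  list(index = idx, right_lateralized = idx <= threshold)
}

#' Count significant voxels in a statistic map
#'
#' @param stat numeric voxel statistics.
#' @param cutoff significance cutoff on the statistic (voxels with
#'   `stat >= cutoff` count as significant).
#' @return Integer count.
#' @export
count_significant_voxels <- function(stat, cutoff) sum(stat >= cutoff)

#' Long-format model table with dummy coding
#'
#' Builds the analysis table behind the condition-effect model: one row per
#' (participant, ROI, condition) response, plus dummy columns coding each
#' non-reference condition against the reference (the reference condition's
#' rows are all-zero). The intended model regresses response on condition
#' with by-participant and by-ROI random intercepts and condition slopes;
#' fitting is delegated to any mixed-model solver, and an ordinary
#' least-squares fit of the fixed part is sufficient for recovery checks.
#'
#' @param responses list of `froi_response` objects.
#' @param reference reference condition (the dummy baseline).
#' @return List with `table` (tibble: `participant`, `roi`, `condition`,
#'   `response`, and one `d_<condition>` column per non-reference
#'   condition) and `coding` (the condition-by-dummy coding matrix).
#' @export
build_model_table <- function(responses, reference = "Sentence") {
  rows <- do.call(rbind, lapply(responses, function(r) {
    tibble::tibble(participant = r$participant, roi = r$roi_label,
                   condition = names(r$response),
                   response = as.numeric(r$response))
  }))
  conds <- unique(rows$condition)
  if (length(conds) < 2L) stop("need at least 2 conditions")
  if (!(reference %in% conds)) {
    stop("reference condition '", reference, "' not present among: ",
         paste(conds, collapse = ", "))
  }
  others <- setdiff(conds, reference)
  coding <- matrix(0, nrow = length(conds), ncol = length(others),
                   dimnames = list(conds, paste0("d_", others)))
  for (o in others) coding[o, paste0("d_", o)] <- 1
  dummies <- coding[rows$condition, , drop = FALSE]
  rownames(dummies) <- NULL
  list(table = cbind(rows, tibble::as_tibble(as.data.frame(dummies))),
       coding = coding)
}

#' Read a voxel map from dense TSV
#'
#' Columns: `voxel_id`, `stat`, then one column per condition.
#'
#' @param path file path; `mask_label` carried onto the result.
#' @export
read_voxel_map_tsv <- function(path, mask_label = NA_character_) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  voxel_map(d$voxel_id, d$stat,
            d[, setdiff(names(d), c("voxel_id", "stat")), drop = FALSE],
            mask_label = mask_label)
}

#' @rdname read_voxel_map_tsv
#' @param m a `voxel_map`.
#' @export
write_voxel_map_tsv <- function(m, path) {
  d <- cbind(data.frame(voxel_id = m$voxel_id, stat = m$localizer_stat),
             m$condition_responses)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a voxel map from NIfTI volumes
#'
#' Builds a `voxel_map` from a statistic volume, a binary mask volume, and
#' one response volume per condition (all same dimensions). Requires the
#' RNifti package.
#'
#' @param stat_path NIfTI path of the localizer statistic map.
#' @param mask_path NIfTI path of the binary mask.
#' @param response_paths named character vector, condition -> NIfTI path.
#' @param mask_label label for the result.
#' @export
read_voxel_map_nifti <- function(stat_path, mask_path, response_paths,
                                 mask_label = NA_character_) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_voxel_map_nifti requires the RNifti package")
  }
  mask <- as.vector(RNifti::readNifti(mask_path)) != 0
  stat <- as.vector(RNifti::readNifti(stat_path))[mask]
  resp <- as.data.frame(lapply(response_paths, function(p)
    as.vector(RNifti::readNifti(p))[mask]))
  names(resp) <- names(response_paths)
  voxel_map(which(mask), stat, resp, mask_label = mask_label)
}
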