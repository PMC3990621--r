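#' The default basic action concept (BAC) catalog for the golf putt
#'
#' The 16 basic action concepts of the putt, each assigned to one
#' biomechanical movement phase. A basic action concept is a cognitive chunk
#' representing a movement posture or event within a complex action; the
#' catalog defines both the item set for the splitting task and the
#' phase-based reference partition used to judge how "functional" a recovered
#' cluster solution is.
#'
#' @param catalog_file Optional path to a CSV with columns `id,label,phase`.
#'   When `NULL` (default) the built-in 16-concept putt catalog is returned.
#' @return A tibble with columns `id` (integer, contiguous from 1), `label`
#'   (character) and `phase` (factor with levels preparation, backswing,
#'   forward_swing, impact, attenuation in movement order).
#' @examples
#' bac_catalog()
#' @export
bac_catalog <- function(catalog_file = NULL) {
  if (is.null(catalog_file)) {
    catalog_file <- system.file("extdata", "bac_catalog_putt.csv",
                                package = "mentalrep", mustWork = TRUE)
  }
  cat_df <- readr::read_csv(catalog_file, show_col_types = FALSE,
                            col_types = readr::cols(
                              id = readr::col_integer(),
                              label = readr::col_character(),
                              phase = readr::col_character()
                            ))
  validate_catalog(cat_df)
}

bac_phases <- c("preparation", "backswing", "forward_swing", "impact",
                "attenuation")

validate_catalog <- function(cat_df) {
  if (!all(c("id", "label", "phase") %in% names(cat_df))) {
    rlang::abort("catalog must have columns id, label, phase",
                 class = "mentalrep_validation_error")
  }
  n <- nrow(cat_df)
  if (!identical(sort(as.integer(cat_df$id)), seq_len(n))) {
    rlang::abort("catalog ids must be contiguous 1..N and unique",
                 class = "mentalrep_validation_error")
  }
  phase_chr <- as.character(cat_df$phase)
  if (anyNA(phase_chr) || any(!nzchar(phase_chr))) {
    rlang::abort("every concept needs exactly one phase label",
                 class = "mentalrep_validation_error")
  }
  lv <- intersect(bac_phases, unique(phase_chr))
  if (length(lv) == 0L) lv <- unique(phase_chr)
  dplyr::arrange(
    tibble::as_tibble(cat_df[c("id", "label", "phase")]),
    .data$id
  ) |>
    dplyr::mutate(id = as.integer(.data$id),
                  phase = factor(.data$phase, levels = lv))
}

#' Movement-phase reference partition
#'
#' Groups the concepts of a catalog by their movement phase. For the default
#' putt catalog this is \{1--4\} preparation, \{5--7\} backswing, \{8,9\}
#' forward swing, \{10--13\} impact, \{14--16\} attenuation: the partition an
#' "optimal", functionally organised mental representation would reproduce.
#'
#' @param catalog A catalog tibble as returned by [bac_catalog()].
#' @return A `partition` object (see [new_partition()]).
#' @examples
#' reference_partition(bac_catalog())
#' @export
reference_partition <- function(catalog = bac_catalog()) {
  catalog <- validate_catalog(catalog)
  blocks <- unname(split(catalog$id, catalog$phase, drop = TRUE))
  new_partition(blocks, n_items = nrow(catalog))
}
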