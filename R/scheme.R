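#' Label schemes for segmented spine volumes
#'
#' A label scheme maps the integer values in a labeled segmentation volume to
#' named anatomical structures and fixes their cranio-caudal order. Vertebrae
#' are listed cranial to caudal; every disc lies between two consecutive
#' vertebrae of that list. Values in `other` (e.g. the spinal canal) are
#' ignored by all measurements.
#'
#' @param vertebrae data.frame with columns `label` (integer) and `name`
#'   (character), ordered cranial to caudal.
#' @param discs data.frame with columns `label`, `name`, `above`, `below`;
#'   `above`/`below` are vertebra names from `vertebrae`, and each disc must
#'   sit between consecutive vertebrae.
#' @param other integer vector of label values to ignore.
#' @return An object of class `label_scheme`.
#' @examples
#' sch <- default_scheme(5)
#' sch$discs
#' @export
label_scheme <- function(vertebrae, discs, other = integer()) {
  stopifnot(is.data.frame(vertebrae), all(c("label", "name") %in% names(vertebrae)),
            is.data.frame(discs), all(c("label", "name", "above", "below") %in% names(discs)))
  vertebrae$label <- as.integer(vertebrae$label)
  discs$label <- as.integer(discs$label)
  all_labels <- c(vertebrae$label, discs$label, as.integer(other))
  if (anyDuplicated(all_labels))
    stop("label values must be unique across the scheme", call. = FALSE)
  if (any(all_labels < 0))
    stop("label values must be non-negative", call. = FALSE)
  vn <- vertebrae$name
  for (i in seq_len(nrow(discs))) {
    ia <- match(discs$above[i], vn)
    ib <- match(discs$below[i], vn)
    if (is.na(ia) || is.na(ib) || ib != ia + 1L)
      stop(sprintf("disc '%s' must lie between consecutive vertebrae of the scheme",
                   discs$name[i]), call. = FALSE)
  }
  # order discs cranial -> caudal by their upper vertebra
  discs <- discs[order(match(discs$above, vn)), , drop = FALSE]
  rownames(discs) <- NULL
  structure(list(vertebrae = vertebrae, discs = discs, other = as.integer(other)),
            class = "label_scheme")
}

#' Default SPIDER-style lumbar label scheme
#'
#' Vertebrae are numbered caudal to cranial starting at 1 (L5 = 1, L4 = 2,
#' ...), discs carry the vertebra-below's number offset by 200, and label 100
#' (spinal canal) is ignored. Levels are named L5 upward (L1, then T12, T11,
#' ... for fields of view extending above the lumbar spine); transitional
#' anatomy is handled by passing a custom scheme instead.
#'
#' @param n_vertebrae number of vertebrae in the field of view.
#' @return A `label_scheme`.
#' @export
default_scheme <- function(n_vertebrae = 5L) {
  stopifnot(n_vertebrae >= 2)
  level_names <- function(n) {
    lumbar <- paste0("L", 5:1)
    thoracic <- paste0("T", 12:1)
    rev(c(lumbar, thoracic)[seq_len(n)]) # cranial -> caudal
  }
  nm <- level_names(n_vertebrae)
  vert <- data.frame(label = seq(n_vertebrae, 1L), name = nm,
                     stringsAsFactors = FALSE)
  nd <- n_vertebrae - 1L
  discs <- data.frame(
    label = 200L + seq(nd, 1L),
    name = paste(nm[-n_vertebrae], nm[-1], sep = "-"),
    above = nm[-n_vertebrae],
    below = nm[-1],
    stringsAsFactors = FALSE
  )
  label_scheme(vert, discs, other = 100L)
}

#' Read or write a label scheme as YAML
#'
#' The file holds three blocks: `vertebrae` (list of `label`/`name`, cranial
#' to caudal), `discs` (list of `label`/`name`/`above`/`below`) and `other`
#' (label values to ignore).
#'
#' @param path file path.
#' @return `read_label_scheme` returns a `label_scheme`;
#'   `write_label_scheme` returns `path` invisibly.
#' @export
read_label_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(x) do.call(rbind.data.frame, c(x, stringsAsFactors = FALSE))
  label_scheme(to_df(y$vertebrae), to_df(y$discs),
               other = as.integer(unlist(y$other)))
}

#' @rdname read_label_scheme
#' @param scheme a `label_scheme`.
#' @export
write_label_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "label_scheme"))
  row_list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  yaml::write_yaml(list(vertebrae = row_list(scheme$vertebrae),
                        discs = row_list(scheme$discs),
                        other = as.list(scheme$other)), path)
  invisible(path)
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme> %d vertebrae (%s ... %s), %d discs, %d ignored label(s)\n",
              nrow(x$vertebrae), x$vertebrae$name[1],
              x$vertebrae$name[nrow(x$vertebrae)], nrow(x$discs),
              length(x$other)))
  invisible(x)
}

# cranial -> caudal vertebra names
scheme_vertebra_order <- function(scheme) scheme$vertebrae$name
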