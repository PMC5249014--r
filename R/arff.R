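#' Write a stage training set to ARFF
#'
#' Numeric attributes in canonical stage order with the class as a final
#' nominal attribute `{negative,positive}` — the layout expected by
#' Weka-style toolkits.
#'
#' @param ts A `stage_training_set` (see [build_stage_training_sets]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arff <- function(ts, path) {
  stopifnot(inherits(ts, "stage_training_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@relation stage%d", ts$stage), con)
  for (nm in colnames(ts$X))
    writeLines(sprintf("@attribute %s numeric", nm), con)
  writeLines("@attribute class {negative,positive}", con)
  writeLines("@data", con)
  rows <- apply(ts$X, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = ","))
  writeLines(paste0(rows, ",", as.character(ts$y)), con)
  invisible(path)
}

#' Read a stage training set from ARFF
#'
#' Inverse of [write_arff]: numeric attributes plus a final nominal class
#' attribute. The stage is inferred from the relation name
#' (`stage1/2/3`) or from the attribute count.
#'
#' @param path Path to an ARFF file.
#' @return A `stage_training_set`.
#' @export
read_arff <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  lower <- tolower(lines)
  rel <- lines[startsWith(lower, "@relation")][1L]
  attr_lines <- lines[startsWith(lower, "@attribute")]
  data_at <- which(lower == "@data")[1L]
  if (is.na(data_at)) stop("no @data section in ", path, call. = FALSE)
  attr_names <- vapply(strsplit(attr_lines, "\\s+"), `[[`, "", 2L)
  is_class <- grepl("\\{", attr_lines)
  if (!is_class[length(is_class)])
    stop("last ARFF attribute must be the nominal class", call. = FALSE)
  feat_names <- attr_names[!is_class]
  rows <- strsplit(lines[(data_at + 1L):length(lines)], ",", fixed = TRUE)
  X <- t(vapply(rows, function(r) as.numeric(r[seq_along(feat_names)]),
                numeric(length(feat_names))))
  colnames(X) <- feat_names
  y <- factor(vapply(rows, function(r) trimws(r[length(r)]), ""),
              levels = c("negative", "positive"))
  stage <- if (grepl("stage[123]", rel))
    as.integer(sub(".*stage([123]).*", "\\1", rel))
  else match(length(feat_names), c(29L, 35L, 80L))
  new_stage_training_set(stage, X, y,
                         ids = paste0("arff_", seq_len(nrow(X))))
}
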