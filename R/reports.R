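#' Genus-by-item report matrix
#'
#' Binary presence of items (scaffold codes or reaction ids) per genus, with
#' each positive cell flagged as literature-reported or model-predicted.
#'
#' @param genus character vector, one entry per record.
#' @param item character vector of item ids (scaffold keys or edge ids).
#' @param status character vector, "reported" or "predicted".
#' @return an object of class \code{report_matrix}: a list with logical
#'   genus-by-item matrices \code{reported} and \code{predicted}.
#' @export
report_matrix <- function(genus, item, status = rep("reported", length(genus))) {
  stopifnot(length(genus) == length(item), length(status) == length(genus))
  bad <- setdiff(unique(status), c("reported", "predicted"))
  if (length(bad)) stop("unknown status: ", paste(bad, collapse = ", "))
  g <- sort(unique(genus)); it <- sort(unique(item))
  rep_m <- matrix(FALSE, length(g), length(it), dimnames = list(g, it))
  pred_m <- rep_m
  isrep <- status == "reported"
  rep_m[cbind(match(genus[isrep], g), match(item[isrep], it))] <- TRUE
  pred_m[cbind(match(genus[!isrep], g), match(item[!isrep], it))] <- TRUE
  structure(list(reported = rep_m, predicted = pred_m), class = "report_matrix")
}

#' @export
print.report_matrix <- function(x, ...) {
  cat("<report_matrix>", nrow(x$reported), "genera x", ncol(x$reported),
      "items;", sum(x$reported), "reported,", sum(x$predicted), "predicted\n")
  invisible(x)
}

#' Extract a plain 0/1 presence matrix from reports
#'
#' @param reports a \code{report_matrix} or a plain binary matrix with genus
#'   rownames (returned unchanged, coerced to 0/1).
#' @param basis "reported" (only literature reports) or "predicted"
#'   (reported together with predicted items).
#' @return an integer 0/1 genus-by-item matrix.
#' @export
presence_matrix <- function(reports, basis = c("reported", "predicted")) {
  basis <- match.arg(basis)
  if (inherits(reports, "report_matrix")) {
    m <- if (basis == "reported") reports$reported
         else reports$reported | reports$predicted
    return(matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m)))
  }
  if (!is.matrix(reports) || is.null(rownames(reports)))
    stop("reports must be a report_matrix or a genus-named binary matrix")
  matrix(as.integer(reports > 0), nrow(reports), ncol(reports),
         dimnames = dimnames(reports))
}

#' Read / write long-format report tables
#'
#' The on-disk format is a CSV with columns \code{genus}, \code{item_id} and
#' \code{status} (\code{reported} or \code{predicted}).
#'
#' @param path file path.
#' @param space optional \code{chem_space}; when given, every item id must
#'   resolve to a node of the space and unknown ids raise an error naming the
#'   offending row.
#' @return \code{read_reports}: a \code{report_matrix}.
#' @export
read_reports <- function(path, space = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genus", "item_id", "status")
  if (!all(need %in% names(df)))
    stop("report CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(space)) {
    unknown <- which(!(df$item_id %in% space$keys))
    if (length(unknown))
      stop("item not in chemical space at row ", unknown[1], ": ",
           df$item_id[unknown[1]])
  }
  report_matrix(df$genus, df$item_id, df$status)
}

#' @rdname read_reports
#' @param reports a \code{report_matrix} to serialize.
#' @export
write_reports <- function(reports, path) {
  stopifnot(inherits(reports, "report_matrix"))
  long <- function(m, status) {
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(genus = rownames(m)[idx[, 1]], item_id = colnames(m)[idx[, 2]],
               status = status, stringsAsFactors = FALSE)
  }
  df <- rbind(long(reports$reported, "reported"),
              long(reports$predicted, "predicted"))
  df <- df[order(df$genus, df$item_id, df$status), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a scaffold-report table of coded structures
#'
#' Reads the curated scaffold-report format: a CSV with columns
#' \code{genus}, \code{scaffold_id} and one column per scaffold carbon
#' (\code{C1}, \code{C3}, ..., \code{C11}) holding oxidation-state tokens
#' such as \code{"1"}, \code{"0+1/4i"} or \code{"2+3/4i"}.  Every code is
#' validated against the grammar; parse or validity failures report the
#' offending line and column.
#'
#' @param path file path.
#' @param grammar an \code{iridoid_grammar}.
#' @return a list with \code{reports} (a \code{report_matrix} whose items are
#'   canonical code keys), \code{records} (the parsed long table) and
#'   \code{codes} (unique codes as a list named by key).
#' @export
read_scaffold_reports <- function(path, grammar = iridoid_grammar()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("genus", "scaffold_id", grammar$carbons)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scaffold-report CSV lacks columns: ", paste(miss, collapse = ", "))
  keys <- character(nrow(df))
  codes <- list()
  for (i in seq_len(nrow(df))) {
    tokens <- as.character(unlist(df[i, grammar$carbons]))
    code <- tryCatch(parse_code(paste(tokens, collapse = ",")),
                     error = function(e)
                       stop("line ", i + 1L, ": ", conditionMessage(e),
                            call. = FALSE))
    v <- validate_code(code, grammar)
    if (!v$valid)
      stop("line ", i + 1L, " (", df$scaffold_id[i], "): ",
           paste(v$violations, collapse = "; "), call. = FALSE)
    keys[i] <- code_key(code)
    codes[[keys[i]]] <- code
  }
  list(reports = report_matrix(df$genus, keys, rep("reported", nrow(df))),
       records = cbind(df[c("genus", "scaffold_id")], key = keys),
       codes = codes)
}
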