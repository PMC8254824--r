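# Readers and writers for the long-format panel and the truth record.
# Panels are tab-delimited text, missing values as empty fields, doubles at
# full (round-trippable) precision.

#' Write a longitudinal panel as delimited text
#'
#' One row per participant-wave; numeric fields are written with 17
#' significant digits so a write/read round trip reproduces them bitwise;
#' missing values are empty fields.
#'
#' @param panel the panel data.frame.
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  out <- panel
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    } else if (is.logical(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "", ifelse(out[[j]], "TRUE", "FALSE"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a longitudinal panel from delimited text
#'
#' Validates the schema: \code{id}, \code{wave} and \code{age} are required,
#' duplicate participant-wave rows are rejected (naming the offending rows),
#' and missing values (empty fields) are preserved as \code{NA}.
#'
#' @param path input file.
#' @param sep field separator.
#' @return the panel data.frame.
#' @export
read_panel <- function(path, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "",
                         stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("id", "wave", "age")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("panel schema violation: missing column(s) ",
         paste(miss, collapse = ", "))
  for (v in c("wave", "age")) {
    if (!is.numeric(x[[v]]))
      stop("panel schema violation: column '", v, "' is not numeric")
  }
  key <- paste(x$id, x$wave, sep = "::")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated participant-wave row(s) at line(s) ",
         paste(dup + 1, collapse = ", "), " (id:wave ",
         paste(unique(key[dup]), collapse = ", "), ")")
  x
}

# --- truth record serialisation ---------------------------------------------
# structured key-value text: one object per line,
#   name|class|dims|comma-separated values (%.17g for doubles)

#' Write a truth record as structured text
#' @param truth a \code{truth_record}.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  fmt1 <- function(v) {
    if (is.character(v)) return(v)
    if (is.integer(v) || is.logical(v)) return(as.character(v))
    sub("^NA$", "NA", sprintf("%.17g", v))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(truth)) {
    v <- truth[[nm]]
    if (is.matrix(v)) {
      dims <- paste(nrow(v), ncol(v), sep = "x")
      cn <- if (!is.null(colnames(v))) paste(colnames(v), collapse = ";") else ""
      writeLines(paste(nm, "matrix", dims, cn,
                       paste(fmt1(as.vector(v)), collapse = ","), sep = "|"), con)
    } else if (is.numeric(v) || is.logical(v)) {
      nms <- if (!is.null(names(v))) paste(names(v), collapse = ";") else ""
      writeLines(paste(nm, class(v)[1], length(v), nms,
                       paste(fmt1(v), collapse = ","), sep = "|"), con)
    }
  }
  invisible(path)
}

#' Read a truth record written by \code{\link{write_truth}}
#' @param path input file.
#' @return a \code{truth_record} list.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "|", fixed = TRUE)[[1]]
    nm <- f[1]; cls <- f[2]; dims <- f[3]; nms <- f[4]
    vals <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (cls == "matrix") {
      d <- as.integer(strsplit(dims, "x")[[1]])
      M <- matrix(as.numeric(vals), d[1], d[2])
      if (nzchar(nms)) colnames(M) <- strsplit(nms, ";")[[1]]
      out[[nm]] <- M
    } else {
      vals[vals == "NA"] <- NA
      v <- switch(cls,
                  integer = as.integer(vals),
                  logical = as.logical(vals),
                  as.numeric(vals))
      if (nzchar(nms)) names(v) <- strsplit(nms, ";")[[1]]
      out[[nm]] <- v
    }
  }
  class(out) <- "truth_record"
  out
}
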