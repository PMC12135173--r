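## TSV dialect used throughout: UTF-8, tab-separated, '#' comments, '.' decimal

#' Read a pattern-count TSV
#'
#' Expected columns: \code{pattern} (binary string over the n marker
#' intervals) and \code{count}.  Marker names are carried in a
#' \code{# markers: a,b,c,...} comment line.  Patterns absent from the file
#' are imputed with count 0 (with a warning).
#'
#' @param path File path.
#' @return A [pattern_dataset()].
#' @export
read_pattern_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  mline <- grep("^#\\s*markers\\s*:", lines, value = TRUE)
  if (length(mline) != 1L)
    stop("expected exactly one '# markers: ...' line in ", path)
  markers <- trimws(strsplit(sub("^#\\s*markers\\s*:", "", mline), ",")[[1L]])
  d <- utils::read.delim(textConnection(lines), comment.char = "#",
                         colClasses = c("character", "numeric"))
  if (!all(c("pattern", "count") %in% names(d)))
    stop("expected columns 'pattern' and 'count' in ", path)
  n <- length(markers) - 1L
  if (nrow(d) < 2^n)
    warning(2^n - nrow(d), " pattern row(s) missing; imputed with count 0")
  pattern_dataset(markers, stats::setNames(d$count, d$pattern))
}

#' Write a pattern-count TSV
#'
#' @param dataset A [pattern_dataset()].
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_pattern_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "xoinv_dataset"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# markers: ", paste(dataset$markers, collapse = ",")),
             con)
  writeLines("pattern\tcount", con)
  writeLines(paste(names(dataset$counts), format(dataset$counts,
                                                 scientific = FALSE,
                                                 trim = TRUE), sep = "\t"),
             con)
  invisible(path)
}

#' Read a chromosome-layout config (YAML)
#'
#' Keys: \code{markers} (list), \code{karyotype} (\code{hetero} or
#' \code{homo}), optional \code{lengths_morgans} and
#' \code{lengths_homo_morgans}, and for heterokaryotypes \code{left_bp},
#' \code{centromere}, \code{right_bp}, each with \code{interval} (1-based)
#' and \code{fraction}.
#'
#' @param path File path.
#' @return A [chromosome_layout()].
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  chromosome_layout(markers = unlist(y$markers),
                    lengths = if (!is.null(y$lengths_morgans))
                      as.numeric(unlist(y$lengths_morgans)),
                    lengths_homo = if (!is.null(y$lengths_homo_morgans))
                      as.numeric(unlist(y$lengths_homo_morgans)),
                    left_bp = y$left_bp, centromere = y$centromere,
                    right_bp = y$right_bp,
                    karyotype = if (is.null(y$karyotype)) "hetero"
                                else y$karyotype)
}

#' Read a sterility TSV
#'
#' Columns: \code{inversion_id}, \code{I_morgans}, \code{rho},
#' \code{observed_sterility}.
#'
#' @param path File path.
#' @return Data frame of sterility records (see [fit_sterility()]).
#' @export
read_sterility <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", encoding = "UTF-8")
  need <- c("inversion_id", "I_morgans", "rho", "observed_sterility")
  if (!all(need %in% names(d)))
    stop("expected columns: ", paste(need, collapse = ", "))
  validate_sterility_records(
    data.frame(inversion_id = d$inversion_id, I = d$I_morgans,
               rho = d$rho, observed = d$observed_sterility))
}

#' Write a sterility TSV
#'
#' @param records Sterility records (columns \code{inversion_id}, \code{I},
#'   \code{rho}, \code{observed}).
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_sterility <- function(records, path) {
  records <- validate_sterility_records(records)
  d <- data.frame(inversion_id = records$inversion_id,
                  I_morgans = records$I, rho = records$rho,
                  observed_sterility = records$observed)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
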