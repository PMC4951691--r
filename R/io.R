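## Tabular readers/writers for the CSV contracts, plus the NCBI accession
## fetcher used for reference sequences.

#' Read a titration series from CSV
#'
#' Expects columns `x`, `y` and optionally `sigma`; a comment line of the
#' form `# kind: quenching` (before the header) sets the series kind.
#'
#' @param path Path to the CSV file.
#' @param kind Overrides the kind from the file header.
#' @return A [TitrationSeries-class].
#' @export
readTitration <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  if (is.null(kind)) {
    m <- regmatches(comments,
                    regexpr("kind:\\s*\\S+", comments))
    kind <- if (length(m)) sub("kind:\\s*", "", m[[1L]]) else "generic"
  }
  tab <- read.table(text = lines[!grepl("^\\s*#", lines)], sep = ",",
                    header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y") %in% colnames(tab)))
  TitrationSeries(tab$x, tab$y, kind = kind,
                  yUncertainty = if ("sigma" %in% colnames(tab))
                    tab$sigma else numeric(0))
}

#' Write a titration series to CSV
#'
#' @param series A [TitrationSeries-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTitration <- function(series, path) {
  stopifnot(is(series, "TitrationSeries"))
  tab <- data.frame(x = series@x, y = series@y)
  if (length(series@yUncertainty)) tab$sigma <- series@yUncertainty
  writeLines(sprintf("# kind: %s", series@kind), path)
  suppressWarnings(write.table(tab, path, append = TRUE, sep = ",",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read a SEC standards table from CSV
#'
#' Expects columns `name`, `Ve` (mL) and at least one of `Rh` (nm),
#' `mass` (Da).
#'
#' @param path Path to the CSV file.
#' @return A data.frame suitable for [calibrateSEC()].
#' @export
readSECTable <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE,
                    comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "Ve") %in% colnames(tab)))
    stop("SEC table needs 'name' and 'Ve' columns")
  if (!any(c("Rh", "mass") %in% colnames(tab)))
    stop("SEC table needs an 'Rh' or 'mass' column")
  tab
}

#' Read a sucrose-gradient table from CSV
#'
#' Expects columns `name`, `position` (fraction index or % sucrose) and
#' `s` (Svedberg).
#'
#' @param path Path to the CSV file.
#' @return A data.frame suitable for [sedimentationFromGradient()].
#' @export
readGradientTable <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE,
                    comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "position", "s") %in% colnames(tab)))
    stop("gradient table needs 'name', 'position' and 's' columns")
  tab
}

#' Fetch a protein sequence from NCBI by accession
#'
#' Downloads the FASTA record for an accession from the NCBI E-utilities
#' efetch endpoint and parses it with [readProteinFasta()]. Requires
#' network access.
#'
#' @param accession Protein accession (e.g. a GenBank identifier).
#' @param timeout Download timeout, seconds.
#' @return An [Biostrings::AAStringSet] with one entry.
#' @export
fetchProteinFasta <- function(accession, timeout = 30) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                "efetch.fcgi?db=protein&rettype=fasta&retmode=text&id=",
                utils::URLencode(accession, reserved = TRUE))
  dest <- tempfile(fileext = ".fasta")
  on.exit(unlink(dest))
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  status <- tryCatch(download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e)
                       stop("could not fetch accession ", accession, ": ",
                            conditionMessage(e), call. = FALSE),
                     warning = function(w)
                       stop("could not fetch accession ", accession, ": ",
                            conditionMessage(w), call. = FALSE))
  if (!identical(status, 0L) || !file.size(dest))
    stop("could not fetch accession ", accession)
  readProteinFasta(dest)
}
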