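# Restriction-enzyme table. The bundled default covers the 20 enzymes the
# CAPS pipeline screens; recognition sequences and top-strand cut offsets
# follow the standard REBASE definitions (e.g. SacI GAGCT^C, AluI AG^CT).
# All bundled recognition sequences are palindromic, so forward-strand
# scanning sees every site.

#' Load a restriction-enzyme table
#'
#' Tab-separated columns: name, recognition (IUPAC string, length >= 4),
#' cut_offset (top-strand cut position within the site, 0..nchar).
#'
#' @param path TSV file; defaults to the bundled 20-enzyme table.
#' @return data.frame with columns name, recognition, cut_offset.
#' @export
#' @examples
#' enz <- load_enzyme_table()
#' enz[enz$name == "SacI", ]
load_enzyme_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "transmark",
                        mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(df)))
    stop("enzyme table must have columns: ", paste(need, collapse = ", "))
  df$recognition <- toupper(df$recognition)
  df$cut_offset <- as.integer(df$cut_offset)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  for (i in seq_len(nrow(df))) {
    letters_i <- strsplit(df$recognition[i], "")[[1]]
    if (!all(letters_i %in% iupac))
      stop("invalid IUPAC letter in recognition sequence of ", df$name[i])
    if (nchar(df$recognition[i]) < 4L)
      stop("recognition sequence of ", df$name[i], " shorter than 4 bp")
    if (is.na(df$cut_offset[i]) || df$cut_offset[i] < 0L ||
        df$cut_offset[i] > nchar(df$recognition[i]))
      stop("cut offset out of range for ", df$name[i])
  }
  df
}
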