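#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the annotation pipeline. Defaults mirror
#' the published web-server guards and filtering constants: a 50,000-base
#' sequence limit, a 1 MiB file limit, a 15% trim fraction for the overlap
#' filter, and a 95% feature-coverage threshold below which a hit is flagged
#' as a possible feature fragment.
#'
#' @param trim_frac Fraction of a winning hit's length trimmed from each side
#'   before lower-scoring hits are tested for intersection. Must satisfy
#'   `0 <= trim_frac < 0.5`.
#' @param fragment_threshold Subject-coverage threshold (fraction of the
#'   library feature's length); hits strictly below it are flagged as
#'   fragments. Must satisfy `0 < fragment_threshold <= 1`.
#' @param max_seq_len Maximum accepted plasmid length in bases.
#' @param max_file_bytes Maximum accepted input file size in bytes.
#' @param topology_default Topology assumed for FASTA/raw input: `"circular"`
#'   or `"linear"`.
#' @param min_anchor_nt Minimum reported alignment length (nucleotide
#'   columns) for the internal nucleotide backend.
#' @param min_anchor_aa Minimum reported alignment length (residue columns)
#'   for the internal translated backend.
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(trim_frac = 0.2)
#' cfg$max_seq_len
pipeline_config <- function(trim_frac = 0.15,
                            fragment_threshold = 0.95,
                            max_seq_len = 50000L,
                            max_file_bytes = 1048576L,
                            topology_default = c("circular", "linear"),
                            min_anchor_nt = 11L,
                            min_anchor_aa = 4L) {
  topology_default <- match.arg(topology_default)
  stopifnot(
    is.numeric(trim_frac), length(trim_frac) == 1, trim_frac >= 0, trim_frac < 0.5,
    is.numeric(fragment_threshold), fragment_threshold > 0, fragment_threshold <= 1,
    is.numeric(max_seq_len), max_seq_len >= 1,
    is.numeric(max_file_bytes), max_file_bytes >= 1,
    min_anchor_nt >= 1, min_anchor_aa >= 1
  )
  structure(
    list(
      trim_frac = as.numeric(trim_frac),
      fragment_threshold = as.numeric(fragment_threshold),
      max_seq_len = as.integer(max_seq_len),
      max_file_bytes = as.integer(max_file_bytes),
      topology_default = topology_default,
      min_anchor_nt = as.integer(min_anchor_nt),
      min_anchor_aa = as.integer(min_anchor_aa)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-19s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# IUPAC nucleotide alphabet accepted in plasmid input (DNA codes only; U is
# deliberately not accepted).
IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

# 20 standard amino acids plus ambiguity/extended codes legal in protein
# library entries.
PROTEIN_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                      "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                      "B", "J", "Z", "X", "U", "O", "*")

abort_input <- function(msg) {
  rlang::abort(msg, class = "plasmidann_input_error")
}
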