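#' Specify an N17-polyQ-tail construct
#'
#' A `construct_spec` captures the sequence assembly rule for the huntingtin
#' exon-1 style constructs analysed throughout the package: the 17-residue
#' N17 domain (optionally carrying one of the four-residue motif variants at
#' positions 14-17), a polyglutamine tract of arbitrary length, and a
#' C-terminal tail (the minimal P5 polyproline tract, the full proline-rich
#' domain, or none).
#'
#' @param polyq_length Number of glutamine residues in the tract (>= 0).
#' @param tail One of `"p5"` (five prolines), `"prd"` (full proline-rich
#'   domain), `"none"`.
#' @param motif_variant Four-letter motif written over N17 positions 14-17;
#'   one of `"LKSF"` (wild type), `"LKAA"`, `"LLLF"`, `"LKGG"`.
#' @param n17_sequence 17-letter N17 sequence; default [HTT_N17].
#' @param tail_sequence Explicit tail sequence overriding the `tail` preset.
#' @return An object of class `"construct_spec"`.
#' @examples
#' sp <- construct_spec(polyq_length = 16)   # N17-Q16-P5, 38 residues
#' build_construct(sp)
#' @seealso [build_construct()], [default_regions()]
#' @export
construct_spec <- function(polyq_length,
                           tail = c("p5", "prd", "none"),
                           motif_variant = "LKSF",
                           n17_sequence = HTT_N17,
                           tail_sequence = NULL) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(polyq_length), length(polyq_length) == 1,
            polyq_length >= 0, polyq_length == round(polyq_length))
  n17_sequence <- toupper(n17_sequence)
  if (nchar(n17_sequence) != 17)
    stop("n17_sequence must have exactly 17 residues, got ",
         nchar(n17_sequence))
  if (!motif_variant %in% names(MOTIF_VARIANTS))
    stop("unknown motif_variant '", motif_variant, "'; choose one of ",
         paste(names(MOTIF_VARIANTS), collapse = ", "))
  if (is.null(tail_sequence)) {
    tail_sequence <- switch(tail,
                            p5   = "PPPPP",
                            prd  = HTT_PRD,
                            none = "")
  } else {
    tail_sequence <- toupper(tail_sequence)
  }
  if (tail == "none" && nchar(tail_sequence) > 0)
    stop("tail = 'none' is inconsistent with a non-empty tail_sequence")
  .check_aa(n17_sequence)
  .check_aa(tail_sequence)

  substr(n17_sequence, 14, 17) <- MOTIF_VARIANTS[[motif_variant]]
  structure(
    list(n17_sequence = n17_sequence,
         polyq_length = as.integer(polyq_length),
         tail = tail,
         tail_sequence = tail_sequence,
         motif_variant = motif_variant),
    class = "construct_spec")
}

.check_aa <- function(s) {
  if (nchar(s) == 0) return(invisible(TRUE))
  bad <- setdiff(strsplit(s, "")[[1]], AA1)
  if (length(bad))
    stop("non-standard amino-acid letters: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Assemble the full amino-acid sequence of a construct
#'
#' Concatenates the (motif-substituted) N17 domain, the polyQ tract and the
#' tail.  Deterministic: the same spec always yields the same string.
#'
#' @param spec A [construct_spec()].
#' @return Single amino-acid string of length
#'   `17 + polyq_length + nchar(tail_sequence)`.
#' @export
build_construct <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  paste0(spec$n17_sequence,
         strrep("Q", spec$polyq_length),
         spec$tail_sequence)
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf("N17(%s)-Q%d-%s construct, %d residues\n",
              x$motif_variant, x$polyq_length,
              switch(x$tail, p5 = "P5", prd = "PRD", none = "(no tail)"),
              17L + x$polyq_length + nchar(x$tail_sequence)))
  invisible(x)
}

#' Annotate a residue range
#'
#' Regions are named, 1-based, inclusive residue ranges used by the kinetics
#' and interaction analyses (for instance the helix-nucleating central
#' region, residues 11-17).
#'
#' @param name Region label.
#' @param start,end 1-based inclusive residue bounds.
#' @return An object of class `"region"`.
#' @export
region <- function(name, start, end) {
  stopifnot(is.character(name), length(name) == 1,
            start >= 1, end >= start)
  structure(list(name = name, start = as.integer(start),
                 end = as.integer(end)),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region '%s': residues %d-%d\n", x$name, x$start, x$end))
  invisible(x)
}

#' Residue indices covered by a region
#' @param x A [region()] (or a plain integer vector, returned as-is).
#' @return Integer vector of residue indices.
#' @export
region_residues <- function(x) {
  if (inherits(x, "region")) return(seq.int(x$start, x$end))
  as.integer(x)
}

#' Default region annotation for a construct
#'
#' Returns the standard partition used throughout the analyses:
#' \describe{
#'   \item{n_terminal_n17}{residues 3-10, the structurally decoupled
#'     N-terminal stretch of N17;}
#'   \item{central}{residues 11-17, the C-terminal N17 stretch that acts as
#'     the helix nucleation site (an extended 11-23 definition reaching into
#'     polyQ can be requested with `central_end`);}
#'   \item{polyq}{residues 18 to `17 + polyq_length`;}
#'   \item{tail}{the remaining C-terminal residues, when present.}
#' }
#'
#' @param spec A [construct_spec()].
#' @param central_end Last residue of the central region (default 17; use 23
#'   for the extended definition spanning the first polyQ residues).
#' @return Named list of [region()] objects.
#' @export
default_regions <- function(spec, central_end = 17L) {
  stopifnot(inherits(spec, "construct_spec"))
  n <- 17L + spec$polyq_length + nchar(spec$tail_sequence)
  regs <- list(
    n_terminal_n17 = region("n_terminal_n17", 3L, 10L),
    central        = region("central", 11L, as.integer(central_end))
  )
  if (spec$polyq_length > 0) {
    regs$polyq <- region("polyq", 18L, 17L + spec$polyq_length)
  }
  if (nchar(spec$tail_sequence) > 0) {
    regs$tail <- region("tail", 18L + spec$polyq_length, n)
  }
  for (r in regs)
    if (r$end > n) stop("region '", r$name, "' exceeds construct length ", n)
  regs
}

#' Export construct sequences as FASTA
#'
#' @param specs A [construct_spec()] or list of them.
#' @param path Output FASTA file.
#' @param names Optional sequence names; defaults to an
#'   `N17(<motif>)-Q<n>-<tail>` label.
#' @return `path`, invisibly.
#' @export
write_construct_fasta <- function(specs, path, names = NULL) {
  if (inherits(specs, "construct_spec")) specs <- list(specs)
  seqs <- lapply(specs, function(sp) strsplit(build_construct(sp), "")[[1]])
  if (is.null(names)) {
    names <- vapply(specs, function(sp)
      sprintf("N17(%s)-Q%d-%s", sp$motif_variant, sp$polyq_length,
              toupper(sp$tail)), character(1))
  }
  seqinr::write.fasta(seqs, names = names, file.out = path)
  invisible(path)
}
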