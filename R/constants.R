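#' Reference sequences and data constants
#'
#' `HTT_N17` is the 17-residue N-terminal amphipathic domain of human
#' huntingtin; positions 14-17 carry the wild-type `LKSF` motif that
#' structurally couples N17 to the downstream polyQ tract.  `HTT_PRD` is the
#' C-terminal proline-rich domain of huntingtin exon-1 (with its P11 and P10
#' polyproline tracts).  Both are editable defaults: any
#' [construct_spec()] field may override them.
#'
#' @format Character scalars (one-letter amino-acid codes).
#' @name reference_sequences
NULL

#' @rdname reference_sequences
#' @export
HTT_N17 <- "MATLEKLMKAFESLKSF"

#' @rdname reference_sequences
#' @export
HTT_PRD <- "PPPPPPPPPPPQLPQPPPQAQPLLPQPQPPPPPPPPPPGPAVAEEPLHRP"

## Four-residue motif variants applied at N17 positions 14-17
MOTIF_VARIANTS <- c(
  LKSF = "LKSF",  # wild type
  LKAA = "LKAA",  # helix-promoting substitution
  LLLF = "LLLF",  # helix-promoting substitution
  LKGG = "LKGG"   # helix-disrupting substitution
)

## DSSP one-letter alphabet; '~' is the coil synonym emitted by some tools
DSSP_CODES <- c("H", "G", "I", "E", "B", "T", "S", "C", "~")

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Random-coil 13C chemical-shift reference
#'
#' Per-residue-type random-coil reference shifts (ppm) for Calpha and Cbeta,
#' Wishart-style values, used by [scsd()] to convert observed shifts into
#' secondary chemical-shift differences.  Glycine has no Cbeta (`NA`).
#' Users with a preferred reference set can pass their own table of the same
#' shape to [scsd()].
#'
#' @format A data.frame with columns `residue_type`, `ca_rc`, `cb_rc`.
#' @export
RANDOM_COIL_SHIFTS <- data.frame(
  residue_type = AA1,
  ca_rc = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0, 61.1,
            55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5, 57.9, 62.2),
  cb_rc = c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9, NA, 29.0, 38.8,
            42.4, 33.1, 32.9, 39.6, 31.9, 63.8, 69.8, 29.6, 38.8, 32.9),
  stringsAsFactors = FALSE
)

## Ideal alpha-helix geometry for the Calpha-trace generator (textbook
## values; only relative geometry matters for angle/contact analyses).
IDEAL_HELIX <- list(
  residues_per_turn = 3.6,
  rise_nm = 0.15,
  radius_nm = 0.23
)

## Backbone atom names (heavy + amide/alpha hydrogens); everything else in a
## standard residue is sidechain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2",
                    "H", "HN", "H1", "H2", "H3", "HA", "HA2", "HA3")
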