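#' Describe an mRNA construct
#'
#' A transcript is characterized, for kinetic purposes, by its length
#' `n_mrna` (nucleotides) and the relative portion `f` of each base in the
#' sequence: each elongation step consumes the four NTPs in proportion
#' `f * n_mrna` per mRNA molecule made. Residue masses convert molar mRNA
#' concentrations to mass yields.
#'
#' @param name Label for the construct.
#' @param n_mrna Transcript length in nucleotides (positive integer).
#' @param f Named numeric vector of base fractions `c(A=, C=, G=, U=)`;
#'   must sum to 1 within 1e-9.
#' @param residue_masses Molar mass (g/mol) of each incorporated residue
#'   (nucleoside monophosphate minus water). Defaults to standard RNA
#'   residue masses.
#' @return An object of class `transcript_spec`.
#' @examples
#' ts <- transcript_spec("demo", 100, c(A = .25, C = .25, G = .25, U = .25))
#' ts$n_mrna
#' @export
transcript_spec <- function(name, n_mrna, f,
                            residue_masses = c(A = 329.2, C = 305.2,
                                               G = 345.2, U = 306.2)) {
  f <- .base_vec(f, "f")
  residue_masses <- .base_vec(residue_masses, "residue_masses")
  .assert_nonneg(f, "f")
  if (any(f > 1)) abort("base fractions must lie in [0, 1]",
                        class = "ivtwin_invalid_input")
  if (abs(sum(f) - 1) > 1e-9) {
    abort(sprintf("base fractions must sum to 1 (got %.12f)", sum(f)),
          class = "ivtwin_invalid_input")
  }
  .assert_finite(n_mrna, "n_mrna")
  if (n_mrna < 1 || n_mrna != round(n_mrna)) {
    abort("`n_mrna` must be a positive integer", class = "ivtwin_invalid_input")
  }
  structure(
    list(name = as.character(name), n_mrna = as.integer(n_mrna),
         f = f, residue_masses = residue_masses),
    class = "transcript_spec"
  )
}

#' @export
print.transcript_spec <- function(x, ...) {
  cat(sprintf("<transcript_spec> %s: %d nt, f = (A %.3f, C %.3f, G %.3f, U %.3f)\n",
              x$name, x$n_mrna, x$f["A"], x$f["C"], x$f["G"], x$f["U"]))
  invisible(x)
}

#' Build a transcript spec from a FASTA sequence
#'
#' Counts bases on the given strand; `T` and `U` are both counted as U, so
#' either a DNA-coded or an RNA sequence can be supplied.
#'
#' @param path Path to a FASTA file (first record is used).
#' @param name Optional construct name; defaults to the FASTA header.
#' @return A [transcript_spec()].
#' @export
transcript_from_fasta <- function(path, name = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("transcript_from_fasta() requires the Biostrings package")
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 1L) abort("no sequences in FASTA file")
  s <- toupper(as.character(seqs[[1L]]))
  if (is.null(name)) name <- names(seqs)[1L]
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  chars[chars == "T"] <- "U"
  bad <- setdiff(unique(chars), .BASES)
  if (length(bad)) {
    abort(paste0("unsupported characters in sequence: ",
                 paste(bad, collapse = ", ")),
          class = "ivtwin_invalid_input")
  }
  n <- length(chars)
  counts <- vapply(.BASES, function(b) sum(chars == b), numeric(1))
  transcript_spec(name, n, counts / n)
}

#' Mean residue molar mass of a transcript
#'
#' @param transcript A [transcript_spec()].
#' @return Composition-weighted residue mass in g/mol.
#' @export
mean_residue_mass <- function(transcript) {
  stopifnot(inherits(transcript, "transcript_spec"))
  sum(transcript$f * transcript$residue_masses)
}

#' Convert between molar and mass concentration of full-length mRNA
#'
#' `mass = c * n_mrna * sum(f_i * residue_mass_i)`, with `c` in mol/L.
#' These converters are the only place unit constants appear; package-wide
#' units are minutes, micromolar and g/L.
#'
#' @param c_umol mRNA concentration in uM.
#' @param g_per_l mRNA concentration in g/L.
#' @param transcript A [transcript_spec()].
#' @return `molar_to_mass()`: g/L; `mass_to_molar()`: uM.
#' @examples
#' ts <- transcript_spec("demo", 4284, c(A = .25, C = .25, G = .25, U = .25))
#' molar_to_mass(7, ts)
#' @export
molar_to_mass <- function(c_umol, transcript) {
  .assert_nonneg(c_umol, "c_umol")
  c_umol * 1e-6 * transcript$n_mrna * mean_residue_mass(transcript)
}

#' @rdname molar_to_mass
#' @export
mass_to_molar <- function(g_per_l, transcript) {
  .assert_nonneg(g_per_l, "g_per_l")
  g_per_l / (1e-6 * transcript$n_mrna * mean_residue_mass(transcript))
}
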