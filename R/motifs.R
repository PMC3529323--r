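.iupac_codes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand one IUPAC nucleotide code to its concrete bases
#'
#' @param letter A single IUPAC code.
#' @return Character vector of compatible bases.
#' @export
iupac_expand <- function(letter) {
  out <- .iupac_codes[[toupper(letter)]]
  if (is.null(out)) {
    abort(paste0("invalid IUPAC code: ", letter),
          class = "retrosig_motif_error")
  }
  out
}

#' @noRd
check_iupac <- function(motif) {
  letters_ <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters_, names(.iupac_codes))
  if (length(bad) > 0) {
    abort(paste0("invalid IUPAC code(s) in motif: ",
                 paste(unique(bad), collapse = ", ")),
          class = "retrosig_motif_error")
  }
  invisible(TRUE)
}

#' Default library of known cis-regulatory motifs
#'
#' Consensus strings for promoter elements commonly scanned in plant
#' stress-response studies: the W-box (WRKY binding site), T-box, the
#' G-box/ABRE core CACGTG, an extended ABRE, the Evening Element of
#' circadian regulation, the light-responsive I-box, the ethylene-responsive
#' GCC-box, and a MYB core. The definitions are editable inputs, not ground
#' truth; replace or extend the tibble (or load one with
#' [read_motif_library()]) to scan other elements.
#'
#' @return Tibble with `name` and `iupac`.
#' @export
motif_library <- function() {
  tibble(
    name = c("w_box", "t_box", "g_box_abre", "abre", "evening_element",
             "i_box", "gcc_box", "myb_core"),
    iupac = c("TTGACY", "ACTTTG", "CACGTG", "ACGTGKC", "AAAATATCT",
              "GATAAG", "GCCGCC", "WAACCA")
  )
}

#' Count occurrences of an IUPAC motif in one sequence
#'
#' Counts distinct start positions (forward coordinates) at which the motif
#' or, with `strands = "both"`, its reverse complement matches under IUPAC
#' degeneracy. A position matching on both strands (palindrome) counts
#' once; overlapping occurrences are allowed. `N` in the sequence matches
#' no motif letter, so masked bases never inflate counts.
#'
#' @param sequence Nucleotide string over A/C/G/T/N.
#' @param motif IUPAC consensus string.
#' @param strands Scan the forward strand only, or both strands.
#' @return Integer occurrence count.
#' @export
scan_motif <- function(sequence, motif, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  motif <- toupper(motif)
  check_iupac(motif)
  subj <- Biostrings::DNAString(toupper(sequence))
  if (nchar(motif) > length(subj)) return(0L)
  starts_of <- function(pat) {
    Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(pat), subj, fixed = "subject"))
  }
  hits <- starts_of(motif)
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    hits <- union(hits, starts_of(rc))
  }
  length(hits)
}

#' Count a motif library across a promoter set
#'
#' @param promoters Tibble with `promoter_id` and `sequence`.
#' @param motifs Motif library tibble (`name`, `iupac`); defaults to
#'   [motif_library()].
#' @inheritParams scan_motif
#' @return Long tibble `promoter_id` x `motif` -> `count`.
#' @export
count_motifs <- function(promoters, motifs = motif_library(),
                         strands = c("both", "forward")) {
  strands <- match.arg(strands)
  tidyr::expand_grid(promoter_id = promoters$promoter_id,
                     motif = motifs$name) |>
    left_join(promoters[c("promoter_id", "sequence")], by = "promoter_id") |>
    left_join(motifs |> rename(motif = "name"), by = "motif") |>
    mutate(count = purrr::map2_int(.data$sequence, .data$iupac,
                                   ~ scan_motif(.x, .y, strands))) |>
    select("promoter_id", "motif", "count")
}

#' Motif over-representation in a foreground promoter set
#'
#' Two modes. `promoter_presence`: a hypergeometric test on the number of
#' promoters containing at least one occurrence, with the pooled foreground
#' plus background promoters as universe (delegates to
#' [enrichment_test()]). `occurrence_rate`: a one-sided binomial test of
#' the total foreground occurrence count against the background per-base
#' occurrence rate (a 0.5 pseudo-occurrence is added to the background to
#' keep the rate positive).
#'
#' @param fg,bg Count tables from [count_motifs()] for the foreground and
#'   background promoter sets (must not share promoter ids).
#' @param mode Test mode.
#' @param promoter_length Bases per promoter, used to convert counts to
#'   per-base rates in `occurrence_rate` mode.
#' @return Tibble with one row per motif: `motif`, `fg_promoters`,
#'   `bg_promoters`, `fg_occurrences`, `bg_occurrences`, `effect`
#'   (fold-enrichment), `p_value`.
#' @export
motif_enrichment <- function(fg, bg,
                             mode = c("promoter_presence", "occurrence_rate"),
                             promoter_length = 1000) {
  mode <- match.arg(mode)
  if (nrow(fg) == 0 || nrow(bg) == 0) {
    abort("foreground and background must be nonempty",
          class = "retrosig_motif_error")
  }
  fg_ids <- unique(fg$promoter_id)
  bg_ids <- unique(bg$promoter_id)
  if (length(intersect(fg_ids, bg_ids)) > 0) {
    abort("foreground and background promoter ids overlap",
          class = "retrosig_motif_error")
  }
  all_counts <- bind_rows(fg, bg)
  per_motif <- function(m) {
    sub <- all_counts |> filter(.data$motif == m)
    x_fg <- sum(sub$count[sub$promoter_id %in% fg_ids])
    x_bg <- sum(sub$count[sub$promoter_id %in% bg_ids])
    if (mode == "promoter_presence") {
      with_hit <- sub$promoter_id[sub$count > 0]
      et <- enrichment_test(fg_ids, with_hit, c(fg_ids, bg_ids))
      tibble(motif = m, fg_promoters = length(fg_ids),
             bg_promoters = length(bg_ids),
             fg_occurrences = x_fg, bg_occurrences = x_bg,
             effect = et$ratio, p_value = et$p_over)
    } else {
      fg_bases <- length(fg_ids) * promoter_length
      bg_bases <- length(bg_ids) * promoter_length
      rate_bg <- (x_bg + 0.5) / bg_bases
      tibble(motif = m, fg_promoters = length(fg_ids),
             bg_promoters = length(bg_ids),
             fg_occurrences = x_fg, bg_occurrences = x_bg,
             effect = (x_fg / fg_bases) / rate_bg,
             p_value = pbinom(x_fg - 1, fg_bases, min(rate_bg, 1),
                              lower.tail = FALSE))
    }
  }
  purrr::map(unique(all_counts$motif), per_motif) |> bind_rows()
}

#' Reverse-complement a nucleotide string
#'
#' @param sequence Nucleotide string (IUPAC codes allowed).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
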