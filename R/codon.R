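# Codon-level machinery shared by the simulator and the Ka/Ks estimator:
# the standard genetic code, NG86 site fractions, and NG86 difference
# partitioning with equal-weight pathway averaging.

.duphist_env <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
genetic_code <- function() {
  gc <- .duphist_env$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- chartr("U", "T", names(gc))
    .duphist_env$genetic_code <- gc
  }
  gc
}

sense_codons <- function() setdiff(names(genetic_code()), STOP_CODONS)

#' Split a CDS string into codons
#'
#' @param cds A coding sequence as a single character string; its length must
#'   be a multiple of 3.
#' @return Character vector of 3-mers.
#' @export
codon_split <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS to protein
#'
#' Translates under the standard genetic code. A single terminal stop codon is
#' dropped; internal stop codons are an error.
#'
#' @param cds Coding sequence (character scalar).
#' @return Protein sequence (character scalar, no stop).
#' @export
translate_cds <- function(cds) {
  codons <- codon_split(cds)
  if (length(codons) == 0L) return("")
  if (codons[length(codons)] %in% STOP_CODONS) codons <- codons[-length(codons)]
  aa <- genetic_code()[codons]
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(aa == "*")) stop("internal stop codon in CDS", call. = FALSE)
  paste(aa, collapse = "")
}

# Drop a single terminal stop codon, validate the rest are sense codons.
sense_codon_vector <- function(cds, what = "CDS") {
  codons <- codon_split(cds)
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  bad <- !(codons %in% names(genetic_code()))
  if (any(bad)) {
    stop(what, " contains invalid codon(s): ",
         paste(unique(codons[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(codons %in% STOP_CODONS)) {
    stop(what, " contains internal stop codon(s)", call. = FALSE)
  }
  codons
}

#' NG86 synonymous/nonsynonymous site counts of one sequence
#'
#' For each codon position the single-nucleotide neighbors are enumerated;
#' changes creating a stop codon are excluded from both numerator and
#' denominator at that position. Each position contributes one site split into
#' a synonymous fraction (synonymous non-stop changes over non-stop changes)
#' and its nonsynonymous complement, so N + S = 3 * L exactly.
#'
#' @param cds Coding sequence or codon vector (terminal stop allowed and
#'   ignored).
#' @return Named numeric vector `c(N = , S = )`.
#' @export
ng86_sites <- function(cds) {
  codons <- if (length(cds) == 1L && nchar(cds[1]) > 3L) {
    sense_codon_vector(cds)
  } else {
    cd <- toupper(cds)
    if (length(cd) && cd[length(cd)] %in% STOP_CODONS) cd <- cd[-length(cd)]
    if (any(cd %in% STOP_CODONS)) stop("stop codon in codon list", call. = FALSE)
    if (!all(cd %in% names(genetic_code()))) stop("invalid codon", call. = FALSE)
    cd
  }
  tab <- ng86_site_table()
  S <- sum(tab[codons])
  c(N = 3 * length(codons) - S, S = S)
}

# Per-codon synonymous site fraction table over the 61 sense codons.
ng86_site_table <- function() {
  tab <- .duphist_env$site_table
  if (!is.null(tab)) return(tab)
  gc <- genetic_code()
  sense <- sense_codons()
  tab <- vapply(sense, function(codon) {
    nt <- strsplit(codon, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(NUCS, nt[pos])
      neigh <- vapply(alts, function(a) {
        x <- nt; x[pos] <- a; paste(x, collapse = "")
      }, character(1))
      keep <- !(neigh %in% STOP_CODONS)
      if (!any(keep)) next  # all neighbors are stops: position fully nonsyn
      syn <- sum(gc[neigh[keep]] == gc[codon])
      s <- s + syn / sum(keep)
    }
    s
  }, numeric(1))
  names(tab) <- sense
  .duphist_env$site_table <- tab
  tab
}

#' NG86 difference counts for a pair of codons
#'
#' Differences between two sense codons are partitioned into synonymous and
#' nonsynonymous counts. Codons differing at k > 1 positions are averaged
#' uniformly over all k! substitution orders; pathways passing through a stop
#' codon are excluded. If every pathway passes through a stop, the k
#' differences are split equally between the two classes.
#'
#' @param codon_a,codon_b Sense codons (3-mers).
#' @return Named numeric vector `c(Nd = , Sd = )`.
#' @export
ng86_codon_diff <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  gc <- genetic_code()
  if (is.na(gc[codon_a]) || is.na(gc[codon_b]) ||
      codon_a %in% STOP_CODONS || codon_b %in% STOP_CODONS) {
    stop("ng86_codon_diff() requires sense codons", call. = FALSE)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) return(c(Nd = 0, Sd = 0))
  perms <- permutations_of(diff_pos)
  nd_tot <- 0; sd_tot <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- a; nd <- 0; sd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (to %in% STOP_CODONS) { ok <- FALSE; break }
      if (gc[from] == gc[to]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { nd_tot <- nd_tot + nd; sd_tot <- sd_tot + sd; n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) return(c(Nd = k / 2, Sd = k / 2))
  c(Nd = nd_tot / n_valid, Sd = sd_tot / n_valid)
}

# All permutations of a short vector (k <= 3 here).
permutations_of <- function(x) {
  k <- length(x)
  if (k == 1L) return(list(x))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# 61 x 61 lookup matrices of Nd and Sd, computed once per session.
ng86_diff_tables <- function() {
  tabs <- .duphist_env$diff_tables
  if (!is.null(tabs)) return(tabs)
  sense <- sense_codons()
  n <- length(sense)
  Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  Sd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) {
        Nd[i, j] <- Nd[j, i]; Sd[i, j] <- Sd[j, i]
      } else if (j > i) {
        d <- ng86_codon_diff(sense[i], sense[j])
        Nd[i, j] <- d[["Nd"]]; Sd[i, j] <- d[["Sd"]]
      }
    }
  }
  tabs <- list(Nd = Nd, Sd = Sd)
  .duphist_env$diff_tables <- tabs
  tabs
}
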