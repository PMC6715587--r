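## Statistics for phosphatase-docking short linear motifs (RVxF, LxxIxE)

AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T",
        "V","W","Y")

#' Background amino-acid frequencies of disordered regions
#'
#' Approximate residue composition of intrinsically disordered regions of the
#' human proteome (enriched in P/S/E/K, depleted in W/C/F/Y/I/V), shipped as
#' the default background for enrichment tests; replace with your own table
#' or use `uniform_background()` where no composition is appropriate.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
disordered_background <- function() {
  f <- c(A = 0.080, C = 0.009, D = 0.058, E = 0.090, F = 0.024, G = 0.072,
         H = 0.021, I = 0.033, K = 0.072, L = 0.063, M = 0.018, N = 0.038,
         P = 0.091, Q = 0.048, R = 0.057, S = 0.094, T = 0.055, V = 0.046,
         W = 0.005, Y = 0.017)
  f / sum(f)
}

#' @rdname disordered_background
#' @export
uniform_background <- function() stats::setNames(rep(1 / 20, 20), AA)

check_peptides <- function(peptides) {
  stopifnot(is.character(peptides), length(peptides) >= 1L)
  L <- unique(nchar(peptides))
  if (length(L) != 1L)
    stop("peptides must all have the same length (aligned frame)", call. = FALSE)
  bad <- !grepl(paste0("^[", paste(AA, collapse = ""), "]+$"), peptides)
  if (any(bad))
    stop("non-standard residue in peptide(s): ",
         paste(peptides[bad], collapse = ", "), call. = FALSE)
  L
}

check_background <- function(background) {
  if (!is.numeric(background) || !setequal(names(background), AA))
    stop("background must be named over the 20 amino acids", call. = FALSE)
  background <- background[AA]
  if (any(background < 0) || abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must be non-negative and sum to 1",
         call. = FALSE)
  background
}

peptide_matrix <- function(peptides) {
  do.call(rbind, strsplit(peptides, ""))
}

#' Position-based similarity weights (Henikoff scheme)
#'
#' Down-weights redundant peptides: at each column a peptide receives
#' `1 / (r * s)` where `r` is the number of distinct residues in the column
#' and `s` the count of the peptide's own residue; weights are summed over
#' columns and normalised to 1.  Identical peptides share weight, a unique
#' peptide gets more than its share.
#'
#' @param peptides Equal-length peptide strings.
#' @return Numeric weights summing to 1.
#' @export
#' @examples
#' peptide_weights(c("RVSF", "RVSF", "KVTF"))  # the distinct peptide > 1/3
peptide_weights <- function(peptides) {
  check_peptides(peptides)
  m <- peptide_matrix(peptides)
  w <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    r <- length(tab)
    w <- w + 1 / (r * as.numeric(tab[m[, j]]))
  }
  w / sum(w)
}

#' Build a position-specific scoring matrix from aligned motif peptides
#'
#' Observed per-column frequencies are similarity-weighted
#' ([peptide_weights()]) and blended with background pseudocounts,
#' `f' = (n f + alpha b) / (n + alpha)` with `n` the peptide count, then
#' scored as natural-log odds against the background.  The pseudocount blend
#' is a data-independent stand-in for information-content-scaled schemes;
#' `alpha` tunes its strength (`alpha -> Inf` recovers the background, score
#' 0 everywhere).
#'
#' @param peptides Equal-length peptide strings.
#' @param background Named frequency vector (default [disordered_background()]).
#' @param alpha Pseudocount weight (default 1).
#' @param weights Optional per-peptide weights (default Henikoff; pass
#'   `rep(1/n, n)` for unweighted frequencies).
#' @return `kp_pssm`: list with `matrix` (positions x 20 log-odds scores),
#'   `freqs`, `background`, `n_peptides`, `weights`, `alpha`.
#' @export
build_pssm <- function(peptides, background = disordered_background(),
                       alpha = 1, weights = NULL) {
  L <- check_peptides(peptides)
  background <- check_background(background)
  if (any(background == 0))
    stop("zero background frequency: log-odds undefined", call. = FALSE)
  stopifnot(alpha >= 0)
  n <- length(peptides)
  if (is.null(weights)) weights <- if (n > 1L) peptide_weights(peptides)
                                   else 1
  stopifnot(length(weights) == n, all(weights >= 0))
  weights <- weights / sum(weights)

  m <- peptide_matrix(peptides)
  freqs <- matrix(0, L, 20, dimnames = list(NULL, AA))
  for (j in seq_len(L))
    freqs[j, ] <- vapply(AA, function(a) sum(weights[m[, j] == a]), numeric(1))
  blend <- (n * freqs + alpha * matrix(background, L, 20, byrow = TRUE)) /
    (n + alpha)
  score <- log(sweep(blend, 2, background, "/"))
  structure(list(matrix = score, freqs = freqs, background = background,
                 n_peptides = n, weights = weights, alpha = alpha),
            class = "kp_pssm")
}

#' Binomial enrichment probability
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p)`: the chance of
#' observing at least the counted number of residues under the background
#' frequency.  Computed via the stable tail of [stats::pbinom()]; valid for
#' `n` up to 1e4 and beyond.  (An enrichment probability must shrink as `k`
#' grows past `n p`; the upper tail is therefore the natural reading of a
#' "binomial(k, n, p)" enrichment, and the point mass is available via
#' `convention = "pmf"`.)
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of motif instances.
#' @param p Background frequency in `[0, 1]`.
#' @param convention `"upper_tail"` (default) or `"pmf"`.
#' @return Probability in `[0, 1]`, vectorised over `k`.
#' @export
#' @examples
#' binomial_enrichment(0, 10, 0.3)   # 1: at least zero is certain
#' binomial_enrichment(8, 10, 0.3)
binomial_enrichment <- function(k, n, p, convention = c("upper_tail", "pmf")) {
  convention <- match.arg(convention)
  if (any(p < 0) || any(p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n", call. = FALSE)
  if (convention == "pmf") return(stats::dbinom(k, n, p))
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

stars_for <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 1e-3, "**", ifelse(p < 0.01, "*", "")))
}

#' Signed log10 relative binomial logo matrix
#'
#' Per position and residue, the signed log10 ratio of the lower to the upper
#' binomial tail, `log10 P(X <= k) - log10 P(X >= k)`: zero when the column
#' matches the background, large and positive for enriched residues, negative
#' for depleted ones.  Letter heights in a log-relative binomial sequence
#' logo are proportional to the magnitude.  Group enrichment (KR basic, DE
#' acidic, ST phosphorylatable) is tested per position with upper-tail
#' probabilities and starred at the 0.01 / 0.001 / 0.0001 tiers.
#'
#' @param peptides Equal-length peptide strings.
#' @param background Named background frequencies.
#' @return `kp_logo`: list with `values` (positions x 20 signed matrix),
#'   `enrichment` (per position/group table with `k`, `n`, `p`, `probability`,
#'   `stars`), `n_peptides`.
#' @export
logo_matrix <- function(peptides, background = disordered_background()) {
  L <- check_peptides(peptides)
  background <- check_background(background)
  n <- length(peptides)
  m <- peptide_matrix(peptides)
  counts <- matrix(0L, L, 20, dimnames = list(NULL, AA))
  for (j in seq_len(L)) {
    tab <- table(factor(m[, j], levels = AA))
    counts[j, ] <- as.integer(tab)
  }
  pu <- matrix(binomial_enrichment(as.vector(counts), n,
                                   rep(background, each = L)), L, 20,
               dimnames = list(NULL, AA))
  pl <- matrix(stats::pbinom(as.vector(counts), n, rep(background, each = L)),
               L, 20, dimnames = list(NULL, AA))
  values <- log10(pl) - log10(pu)

  groups <- list(KR = c("K", "R"), DE = c("D", "E"), ST = c("S", "T"))
  enr <- do.call(rbind, lapply(names(groups), function(g) {
    res <- groups[[g]]
    k <- rowSums(counts[, res, drop = FALSE])
    p <- sum(background[res])
    prob <- binomial_enrichment(k, n, p)
    data.frame(position = seq_len(L), target = g, k = k, n = n, p = p,
               probability = prob, stars = stars_for(prob))
  }))
  structure(list(values = values, enrichment = enr, n_peptides = n),
            class = "kp_logo")
}

#' Significance stars for an enrichment probability
#'
#' Tiers: `*` p < 0.01, `**` p < 0.001, `***` p < 0.0001.
#'
#' @param probability Probability value(s).
#' @return Character vector of stars (empty string when not significant).
#' @export
enrichment_stars <- function(probability) stars_for(probability)

#' Kinase-class annotation of a phosphosite
#'
#' Applies, in order, the basophilic (`[KR]xS` or `[KR]xxS`), acidophilic
#' (`[DEN]x[ST]`) and proline-directed (`[ST]P`) consensus patterns anchored
#' on the site; all matching labels are returned, the first being the primary
#' call, with `"other"` when none matches.
#'
#' @param peptide Peptide string.
#' @param position 1-based position of the phosphosite within `peptide`;
#'   must hold S or T.
#' @return Character vector of labels (primary first).
#' @export
#' @examples
#' classify_kinase_site("RAS", 3)  # basophilic
#' classify_kinase_site("DGT", 3)  # acidophilic
#' classify_kinase_site("ASP", 2)  # proline_directed
classify_kinase_site <- function(peptide, position) {
  chars <- strsplit(peptide, "")[[1L]]
  if (position < 1L || position > length(chars))
    stop("position out of range", call. = FALSE)
  site <- chars[position]
  if (!(site %in% c("S", "T")))
    stop("phosphosite must be S or T (got '", site, "')", call. = FALSE)
  labels <- character()
  at <- function(i) if (i >= 1L && i <= length(chars)) chars[i] else ""
  if (site == "S" && (at(position - 2L) %in% c("K", "R") ||
                      at(position - 3L) %in% c("K", "R")))
    labels <- c(labels, "basophilic")
  if (at(position - 2L) %in% c("D", "E", "N"))
    labels <- c(labels, "acidophilic")
  if (at(position + 1L) == "P")
    labels <- c(labels, "proline_directed")
  if (!length(labels)) labels <- "other"
  labels
}

#' Motif table reader
#'
#' Reads a TSV of aligned motif instances with columns `protein_id`,
#' `peptide`, `class`, `phosphosites` (semicolon-separated 1-based in-frame
#' positions, empty when none validated), `source` (`validated`/`predicted`).
#'
#' @param path TSV path.
#' @return `kp_motifs` data.frame with a `phosphosites` list-column of
#'   integer vectors.
#' @export
read_motif_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c(phosphosites = "character"))
  need <- c("protein_id", "peptide", "class", "phosphosites", "source")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("motif table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  L <- check_peptides(d$peptide)
  sites <- lapply(d$phosphosites, function(s) {
    if (is.na(s) || !nzchar(s)) return(integer())
    as.integer(strsplit(s, ";")[[1L]])
  })
  for (i in seq_along(sites)) {
    ps <- sites[[i]]
    if (any(ps < 1L | ps > L))
      stop("phosphosite outside the motif frame in row ", i, call. = FALSE)
    res <- strsplit(d$peptide[i], "")[[1L]][ps]
    if (any(!(res %in% c("S", "T", "Y"))))
      stop("phosphosite on a non-phosphorylatable residue in row ", i,
           call. = FALSE)
  }
  d$phosphosites <- sites
  class(d) <- c("kp_motifs", "data.frame")
  d
}

#' Default motif-region windows
#'
#' The in-frame positions where phosphorylation is known to modulate
#' phosphatase binding: for RVxF the 8-position core window; for LxxIxE the
#' 6-position core plus the 3 positions immediately downstream (where
#' phosphate groups contact the basic groove on B56).
#'
#' @param motif_class `"RVxF"` or `"LxxIxE"`.
#' @return Integer vector of frame positions.
#' @export
motif_region <- function(motif_class = c("RVxF", "LxxIxE")) {
  motif_class <- match.arg(motif_class)
  switch(motif_class, RVxF = 1:8, LxxIxE = 1:9)
}

#' Phosphorylated and phosphorylatable motif fractions in a region
#'
#' Fraction of motifs with at least one experimentally validated phosphosite
#' inside the region (phosphorylated), and with at least one S/T residue at a
#' region position (phosphorylatable).  The former can never exceed the
#' latter.
#'
#' @param motifs A `kp_motifs` data.frame ([read_motif_table()]).
#' @param region Integer frame positions (default per motif class).
#' @return Named numeric: `phosphorylated`, `phosphorylatable` (fractions).
#' @export
phospho_summary <- function(motifs, region = NULL) {
  if (!nrow(motifs)) stop("empty motif list", call. = FALSE)
  if (is.null(region)) {
    cls <- unique(motifs$class)
    if (length(cls) != 1L)
      stop("supply an explicit region for mixed motif classes", call. = FALSE)
    region <- motif_region(cls)
  }
  L <- nchar(motifs$peptide[1L])
  if (any(region < 1L | region > L))
    stop("region outside the motif frame", call. = FALSE)
  phos <- vapply(motifs$phosphosites, function(ps) any(ps %in% region),
                 logical(1))
  able <- vapply(motifs$peptide, function(p) {
    any(strsplit(p, "")[[1L]][region] %in% c("S", "T"))
  }, logical(1))
  c(phosphorylated = mean(phos), phosphorylatable = mean(able))
}

#' Write a PSSM or logo matrix as TSV
#'
#' @param x A `kp_pssm` or `kp_logo`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pssm_tsv <- function(x, path) {
  m <- if (inherits(x, "kp_pssm")) x$matrix else x$values
  d <- data.frame(position = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
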