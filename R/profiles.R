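#' Top-K transcription-factor profiles of a differential gene set
#'
#' For each TF in the regulation table, counts how many of the given
#' differential genes it is documented to regulate, keeps the top `K` TFs
#' by that count (default 20), and carries each TF's fraction of the total
#' differential gene count. TFs regulating none of the genes never appear;
#' ties at the K-th rank are broken lexicographically by TF name so the
#' profile is deterministic. The fraction denominator is the full
#' differential set, including genes no TF regulates.
#'
#' @param de_genes nonempty character vector of differential gene ids.
#' @param regulation a [regulation_table()].
#' @param K profile size cap (default 20).
#' @param label comparison label carried on the profile.
#' @return object of class `"tf_profile"`: data.frame with columns `tf`,
#'   `n_targets_in_de`, `fraction`, sorted by count descending then TF
#'   name; attributes `label`, `n_de_total`, `K`.
#' @examples
#' reg <- regulation_table(c("A", "A", "A", "B", "B"),
#'                         c("g1", "g2", "g3", "g4", "g5"),
#'                         rep("documented-direct", 5))
#' build_profile(c("g1", "g2", "g3", "g4", "g5"), reg)
#' @export
build_profile <- function(de_genes, regulation, K = 20,
                          label = "comparison") {
  stopifnot(inherits(regulation, "regulation_table"))
  de_genes <- unique(as.character(de_genes))
  if (!length(de_genes))
    stop_input("`de_genes` is empty: profile fractions are undefined")
  if (K < 1) stop_config("K must be >= 1")
  hits <- unique(as.data.frame(regulation)[
    regulation$target %in% de_genes, c("tf", "target")])
  counts <- vapply(split(hits$target, hits$tf), length, integer(1))
  ord <- order(-counts, names(counts))
  counts <- counts[ord][seq_len(min(K, length(counts)))]
  df <- data.frame(tf = names(counts),
                   n_targets_in_de = as.integer(counts),
                   fraction = as.numeric(counts) / length(de_genes),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, label = label, n_de_total = length(de_genes), K = K,
            class = c("tf_profile", "data.frame"))
}

#' @export
print.tf_profile <- function(x, ...) {
  cat(sprintf("TF profile [%s]: top %d of cap %d, %d DE genes\n",
              attr(x, "label"), nrow(x), attr(x, "K"), attr(x, "n_de_total")))
  print(as.data.frame(x), right = FALSE)
  invisible(x)
}

#' @export
plot.tf_profile <- function(x, ...) {
  graphics::barplot(rev(x$fraction), names.arg = rev(x$tf), horiz = TRUE,
                    las = 1, xlab = "fraction of DE genes regulated",
                    main = attr(x, "label"), ...)
  invisible(x)
}

#' Align two TF profiles on a shared axis and normalize to unit length
#'
#' The shared axis is the lexicographically sorted union of the two
#' profiles' TF names; each profile's fractions are placed on that axis
#' (0 where the TF is absent) and the vector is rescaled to unit length —
#' Euclidean (L2) by default, so that profile distances are scale-free and
#' bounded by sqrt(2); L1 is available as an alternative.
#'
#' @param p1,p2 [build_profile()] results with at least one entry each.
#' @param norm `"l2"` (default) or `"l1"`.
#' @return list of two objects of class `"normalized_profile"`, each a
#'   list with `axis` (TF names) and `vector` (nonnegative, unit norm),
#'   plus the originating `label`.
#' @export
align_and_normalize <- function(p1, p2, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  stopifnot(inherits(p1, "tf_profile"), inherits(p2, "tf_profile"))
  if (!nrow(p1) || !nrow(p2))
    stop_input("both profiles need at least one entry")
  axis <- sort(union(p1$tf, p2$tf))
  place <- function(p) {
    v <- stats::setNames(numeric(length(axis)), axis)
    v[p$tf] <- p$fraction
    nrm <- if (norm == "l2") sqrt(sum(v^2)) else sum(abs(v))
    stopifnot(nrm > 0)  # impossible for nonempty profiles
    structure(list(axis = axis, vector = unname(v / nrm),
                   label = attr(p, "label")),
              class = "normalized_profile")
  }
  list(place(p1), place(p2))
}

#' Euclidean distance between two aligned normalized profiles
#'
#' `d = sqrt(sum_i (s_i - r_i)^2)` over the shared TF axis. For
#' nonnegative unit (L2) vectors, d lies in `[0, sqrt(2)]`: 0 iff the
#' profiles are identical, sqrt(2) iff their supports are disjoint.
#'
#' @param s,r `normalized_profile` objects on identical axes.
#' @return nonnegative distance.
#' @export
profile_distance <- function(s, r) {
  stopifnot(inherits(s, "normalized_profile"),
            inherits(r, "normalized_profile"))
  if (!identical(s$axis, r$axis))
    stop_design("profiles are on different TF axes; align them first")
  sqrt(sum((s$vector - r$vector)^2))
}

#' @rdname profile_distance
#' @param p1,p2 raw [build_profile()] results; aligned and normalized
#'   before the distance is taken.
#' @inheritParams align_and_normalize
#' @export
tf_profile_distance <- function(p1, p2, norm = c("l2", "l1")) {
  np <- align_and_normalize(p1, p2, match.arg(norm))
  profile_distance(np[[1]], np[[2]])
}

#' Conserved TFs: intersection of profiles across comparisons
#'
#' The TFs present in the top-K profile of every comparison — the
#' regulators recruited regardless of condition, the "conserved module"
#' readout of the analysis. Order-independent and idempotent under
#' duplicated profiles.
#'
#' @param profiles nonempty list of `tf_profile` objects.
#' @return sorted character vector of TF names.
#' @export
conserved_tfs <- function(profiles) {
  if (!length(profiles)) stop_input("need at least one profile")
  sets <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "tf_profile"))
    p$tf
  })
  sort(Reduce(intersect, sets))
}

#' Reference TF profile from the head of a ranked gene list
#'
#' Builds a [build_profile()] over the first `n_ref_genes` genes (default
#' 250) of an externally ranked differential-expression list, producing
#' the landmark profile that sample profiles are compared against by
#' Euclidean distance.
#'
#' @param ranked_genes full ranked gene list, best first.
#' @param regulation a [regulation_table()].
#' @param n_ref_genes head size (default 250).
#' @param K profile cap (default 20).
#' @param label label for the reference profile.
#' @return a `tf_profile`.
#' @export
build_reference_profile <- function(ranked_genes, regulation,
                                    n_ref_genes = 250, K = 20,
                                    label = "reference") {
  ranked_genes <- as.character(ranked_genes)
  if (length(ranked_genes) < n_ref_genes)
    stop_input("ranking has ", length(ranked_genes),
               " genes, fewer than n_ref_genes = ", n_ref_genes)
  build_profile(ranked_genes[seq_len(n_ref_genes)], regulation, K = K,
                label = label)
}

#' @rdname build_profile
#' @param x a `tf_profile`.
#' @param path output TSV path; a `#` header carries label, n_de_total, K.
#' @export
write_tf_profile <- function(x, path) {
  stopifnot(inherits(x, "tf_profile"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# label=%s n_de_total=%d K=%d",
                     attr(x, "label"), attr(x, "n_de_total"), attr(x, "K")),
             con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
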