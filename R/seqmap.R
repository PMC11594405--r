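# Glocal sequence alignment, percent identity, and residue mapping onto
# full-length predicted models.
#
# The alignment contract is global in the domain (query) with free end gaps
# in the reference protein: the domain must be wholly explained while the
# full-length protein contributes a window. This is Biostrings'
# "global-local" type; gap cost for a run of length k is open + k * extend.

#' Alignment parameters
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped);
#'   the unknown residue `X` scores 0 against everything.
#' @param gap_open,gap_extend affine gap penalties (cost of a length-k gap is
#'   `gap_open + k * gap_extend`). Defaults 10 and 0.2.
#' @param mode alignment mode; only `"glocal"` is supported.
#' @return object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 0.2, mode = "glocal") {
  if (gap_open < 0 || gap_extend < 0)
    stop_fc("gap penalties must be non-negative", "fc_validation_error")
  if (mode != "glocal") stop_fc("only glocal mode is supported", "fc_validation_error")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "alignment_params")
}

subst_matrix <- function(name = "BLOSUM62") {
  if (name != "BLOSUM62")
    stop_fc("unsupported substitution matrix", "fc_validation_error")
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

check_alphabet <- function(seqs) {
  ok <- grepl(paste0("^[", paste(AA1, collapse = ""), "X]+$"), seqs)
  if (!all(ok))
    stop_fc("sequence contains characters outside the amino-acid alphabet + X",
            "fc_validation_error")
}

#' Glocal pairwise alignment of a domain sequence to a reference
#'
#' Optimal affine-gap alignment that is global in `query` and has free end
#' gaps in `reference`, computed with Biostrings' dynamic programming
#' (`type = "global-local"`).
#'
#' @param query domain sequence (uppercase one-letter codes, `X` allowed).
#' @param reference full-length reference sequence.
#' @param params an [alignment_params()].
#' @return object of class `alignment_result`: `aligned_pairs` (two-column
#'   matrix of matched query/reference positions, strictly increasing in
#'   both), `score`, `query_span`, `reference_span`, and the aligned strings.
#' @export
align_glocal <- function(query, reference, params = alignment_params()) {
  if (nchar(query) == 0 || nchar(reference) == 0)
    stop_fc("sequences must be non-empty", "fc_validation_error")
  check_alphabet(c(query, reference))
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global-local",
    substitutionMatrix = subst_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  qa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-") + Biostrings::start(Biostrings::subject(pa)) - 1L
  matched <- qa != "-" & ra != "-"
  pairs <- cbind(query_pos = qpos[matched], reference_pos = rpos[matched])
  structure(list(aligned_pairs = pairs, score = Biostrings::score(pa),
                 query_span = c(1L, nchar(query)),
                 reference_span = c(Biostrings::start(Biostrings::subject(pa)),
                                    Biostrings::end(Biostrings::subject(pa))),
                 query_aln = paste(qa, collapse = ""),
                 reference_aln = paste(ra, collapse = "")),
            class = "alignment_result")
}

#' Percent identity over matched alignment columns
#'
#' Gap columns are excluded from both numerator and denominator.
#'
#' @param a an `alignment_result`.
#' @param query,reference the sequences it was computed from.
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, query, reference) {
  p <- a$aligned_pairs
  if (nrow(p) == 0) stop_fc("no matched columns: PID undefined", "fc_undefined_pid")
  q <- strsplit(query, "")[[1]][p[, 1]]
  r <- strsplit(reference, "")[[1]][p[, 2]]
  100 * sum(q == r) / nrow(p)
}

#' Build the one-on-one residue map between an instance and a model
#'
#' Matched (non-gap) alignment columns are turned into residue pairs; a
#' model residue is addressed by its ordinal position along the model chain,
#' which for full-length predicted models equals the reference-sequence
#' position. Pairs whose model residue lacks a CA atom are dropped with a
#' warning.
#'
#' @param inst a `domain_instance` whose sequence was the alignment query.
#' @param model a `structure_model` of the full-length predicted protein.
#' @param a the `alignment_result` of `inst$seq` against the model's
#'   reference sequence.
#' @return a `residue_map`: data frame `inst_key`, `model_key`, `inst_pos`,
#'   `ref_pos` with attribute `pid`.
#' @export
build_residue_map <- function(inst, model, a) {
  p <- a$aligned_pairs
  if (nrow(p) == 0) stop_fc("empty alignment", "fc_empty_map")
  ri <- residue_table(inst)
  mt <- model_residue_table(model)
  ok_model <- p[, 2] <= nrow(mt)
  p <- p[ok_model, , drop = FALSE]
  inst_key <- ri$key[p[, 1]]
  model_key <- mt$key[p[, 2]]
  has_ca <- mt$has_ca[p[, 2]] & ri$has_ca[p[, 1]]
  if (any(!has_ca))
    warning(sum(!has_ca), " mapped pair(s) dropped for missing CA atoms")
  keep <- has_ca
  if (!any(keep)) stop_fc("no mappable residues with CA", "fc_empty_map")
  ref_seq <- paste(mt$aa, collapse = "")
  pid <- percent_identity(a, inst$seq, ref_seq)
  structure(data.frame(inst_key = inst_key[keep], model_key = model_key[keep],
                       inst_pos = p[keep, 1], ref_pos = p[keep, 2],
                       stringsAsFactors = FALSE),
            class = c("residue_map", "data.frame"), pid = pid)
}

model_residue_table <- function(model) {
  a <- model$atoms
  keys <- unique(a$key)
  idx <- match(keys, a$key)
  data.frame(key = keys, aa = a$aa[idx],
             has_ca = keys %in% a$key[a$elety == "CA"],
             stringsAsFactors = FALSE)
}

#' Extract the predicted-structure counterpart of a domain
#'
#' Pulls the mapped residues out of the full-length predicted model, in
#' reference order, keeping per-residue confidence (pLDDT) in the B-factor
#' column.
#'
#' @param model full-length predicted `structure_model`.
#' @param m a `residue_map` from [build_residue_map()].
#' @param like optional experimental `domain_instance` whose definition
#'   metadata (domain id, CATH codes, accession) is copied onto the result.
#' @return a predicted `domain_instance` with `window` set to the mapped
#'   reference-position range.
#' @export
extract_predicted_domain <- function(model, m, like = NULL) {
  if (nrow(m) == 0) stop_fc("empty residue map", "fc_empty_map")
  m <- m[order(m$ref_pos), , drop = FALSE]
  at <- model$atoms[model$atoms$key %in% m$model_key, , drop = FALSE]
  at <- at[order(match(at$key, m$model_key)), , drop = FALSE]
  d <- if (is.null(like)) {
    domain_definition("predicted", "0.0.0.0", model$source_id,
                      data.frame(chain = at$chain[1], start = min(at$resno),
                                 end = max(at$resno)))
  } else {
    structure(list(domain_id = like$domain_id, cath_code = like$cath_code,
                   topology_code = like$topology_code,
                   segments = data.frame(chain = at$chain[1],
                                         start = min(at$resno),
                                         end = max(at$resno)),
                   protein_acc = like$protein_acc),
              class = "domain_definition")
  }
  inst <- new_domain_instance(at, d, model, is_predicted = TRUE)
  inst$window <- range(m$ref_pos)
  inst
}
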