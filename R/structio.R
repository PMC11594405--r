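# Structure ingestion, domain extraction and curation.
#
# Structures are held as a light S3 container around an atom table (one row
# per atom, bio3d-style columns) rather than a nested residue tree; residue
# identity is author numbering + insertion code, the PDB convention.

#' Read an experimental or predicted structure
#'
#' Parses a PDB or mmCIF file into a `structure_model`: an atom table for
#' polymer residues, a separate table for heteroatom groups (waters dropped),
#' plus method and resolution pulled from the header when present. For
#' multi-model (NMR) files only the first model is used. Alternate-location
#' atoms are reduced to the highest-occupancy copy.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param source_id identifier to record; defaults to the file stem.
#' @return an object of class `structure_model` with elements `source_id`,
#'   `method`, `resolution` (Angstrom or `NA`), `atoms` and `het_atoms`
#'   (data frames with columns `chain`, `resno`, `insert`, `resid`, `aa`,
#'   `elety`, `elesy`, `x`, `y`, `z`, `o`, `b`, `key`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fc(paste0("file not found: ", path), "fc_io_error")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_fc(paste0("cannot parse ", path, " as ", format,
                                       ": ", conditionMessage(e)),
                                "fc_format_error"))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0)
    stop_fc(paste0("no atoms in ", path), "fc_empty_structure")
  hdr <- read_structure_header(path, format)
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  at$insert[is.na(at$insert) | at$insert == "?"] <- ""
  if (is.null(at$elesy) || all(is.na(at$elesy)))
    at$elesy <- guess_element(at$elety)
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- guess_element(
    at$elety[is.na(at$elesy) | at$elesy == ""])
  at$o[is.na(at$o)] <- 1
  at <- drop_altloc(at)
  key <- res_key(at$chain, at$resno, at$insert)
  tab <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                    resid = at$resid, aa = aa_three_to_one(at$resid),
                    elety = at$elety, elesy = toupper(at$elesy),
                    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
                    key = key, stringsAsFactors = FALSE)
  is_het <- at$type == "HETATM" & !(toupper(at$resid) %in% names(AA3TO1))
  het <- tab[is_het, , drop = FALSE]
  het <- het[!(toupper(het$resid) %in% WATER_RESIDS), , drop = FALSE]
  structure(list(source_id = source_id %||% sub("\\.[^.]*$", "", basename(path)),
                 method = hdr$method, resolution = hdr$resolution,
                 atoms = tab[!is_het, , drop = FALSE], het_atoms = het),
            class = "structure_model")
}

# bio3d does not surface resolution/method; scan header lines directly.
read_structure_header <- function(path, format) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  method <- NA_character_; resolution <- NA_real_
  if (format == "pdb") {
    ex <- grep("^EXPDTA", lines, value = TRUE)
    if (length(ex)) method <- trimws(sub("^EXPDTA\\s*", "", ex[1]))
    rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rl)) {
      num <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
      if (length(num)) resolution <- as.numeric(num)
    }
  } else {
    ml <- grep("_exptl\\.method", lines, value = TRUE)
    if (length(ml)) method <- gsub("['\"]", "", trimws(sub(".*_exptl\\.method", "", ml[1])))
    rl <- grep("_refine\\.ls_d_res_high|_em_3d_reconstruction\\.resolution", lines,
               value = TRUE)
    if (length(rl)) {
      num <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
      if (length(num)) resolution <- as.numeric(num)
    }
  }
  list(method = method, resolution = resolution)
}

guess_element <- function(elety) {
  e <- toupper(substr(trimws(elety), 1, 2))
  out <- ifelse(e %in% names(VDW_RADII) & !substr(e, 1, 1) %in% c("C", "N", "O", "S", "P", "H"),
                e, substr(e, 1, 1))
  out
}

# keep highest-occupancy alternate location per (residue, atom name)
drop_altloc <- function(at) {
  id <- paste(at$chain, at$resno, at$insert, at$elety, at$type)
  if (!anyDuplicated(id)) return(at)
  ord <- order(id, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(id[ord]), , drop = FALSE]
  at[order(as.integer(rownames(at))), , drop = FALSE]
}

#' Read CATH-style domain definitions from a TSV file
#'
#' Expects columns `domain_id`, `cath_code`, `protein_acc` and `segments`.
#' `segments` holds one or more `chain:start-end` ranges separated by commas
#' (author residue numbering, inclusive). The three-level topology code is
#' derived from the four-level CATH code.
#'
#' @param path TSV file with a header row.
#' @return list of `domain_definition` objects.
#' @export
read_domain_definitions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_id", "cath_code", "protein_acc", "segments")
  if (!all(need %in% names(df)))
    stop_fc(paste0("domain definition table must have columns: ",
                   paste(need, collapse = ", ")), "fc_validation_error")
  lapply(seq_len(nrow(df)), function(i)
    domain_definition(df$domain_id[i], df$cath_code[i], df$protein_acc[i],
                      df$segments[i]))
}

#' Construct a domain definition
#'
#' @param domain_id unique label for the definition.
#' @param cath_code four-level `C.A.T.H` code (dot-separated integers).
#' @param protein_acc reference-protein accession the domain belongs to.
#' @param segments either a string `"A:5-60,A:70-120"` or a data frame with
#'   columns `chain`, `start`, `end`.
#' @return object of class `domain_definition`.
#' @export
domain_definition <- function(domain_id, cath_code, protein_acc, segments) {
  parts <- strsplit(cath_code, ".", fixed = TRUE)[[1]]
  if (length(parts) != 4 || anyNA(suppressWarnings(as.integer(parts))))
    stop_fc(paste0("malformed CATH code '", cath_code,
                   "': need 4 dot-separated integers"), "fc_validation_error")
  if (is.character(segments)) segments <- parse_segments(segments)
  if (nrow(segments) < 1) stop_fc("need at least one segment", "fc_validation_error")
  if (any(segments$end < segments$start))
    stop_fc("segment end before start", "fc_validation_error")
  for (ch in unique(segments$chain)) {
    s <- segments[segments$chain == ch, , drop = FALSE]
    if (nrow(s) > 1) {
      s <- s[order(s$start), , drop = FALSE]
      if (any(s$start[-1] <= s$end[-nrow(s)]))
        stop_fc(paste0("overlapping segments on chain ", ch), "fc_validation_error")
    }
  }
  structure(list(domain_id = domain_id, cath_code = cath_code,
                 topology_code = paste(parts[1:3], collapse = "."),
                 segments = segments, protein_acc = protein_acc),
            class = "domain_definition")
}

parse_segments <- function(txt) {
  pieces <- strsplit(txt, ",", fixed = TRUE)[[1]]
  m <- regmatches(pieces, regexec("^\\s*([^:]+):(-?[0-9]+)-(-?[0-9]+)\\s*$", pieces))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop_fc(paste0("cannot parse segment(s): ", paste(pieces[bad], collapse = "; ")),
            "fc_validation_error")
  data.frame(chain = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Extract one domain instance from a structure
#'
#' Selects the residues falling inside the definition's segments (inclusive
#' author-number ranges), in segment order. Unresolved residues are silently
#' absent; the instance sequence is rebuilt from the residues actually
#' present.
#'
#' @param s a `structure_model`.
#' @param d a `domain_definition`.
#' @param is_predicted flag stored on the instance.
#' @return object of class `domain_instance` with the atom table restricted
#'   to the domain, `seq`, `n_res`, `n_segments`, provenance and resolution.
#' @export
extract_domain_instance <- function(s, d, is_predicted = FALSE) {
  stopifnot(inherits(s, "structure_model"), inherits(d, "domain_definition"))
  at <- s$atoms
  keep <- vector("list", nrow(d$segments))
  for (i in seq_len(nrow(d$segments))) {
    seg <- d$segments[i, ]
    sel <- at$chain == seg$chain & at$resno >= seg$start & at$resno <= seg$end
    sub <- at[sel, , drop = FALSE]
    sub <- sub[order(sub$resno, sub$insert), , drop = FALSE]
    keep[[i]] <- sub
  }
  atoms <- do.call(rbind, keep)
  if (is.null(atoms) || nrow(atoms) == 0)
    stop_fc(paste0("no residues of ", s$source_id, " fall in the segments of ",
                   d$domain_id), "fc_empty_domain")
  new_domain_instance(atoms, d, s, is_predicted)
}

new_domain_instance <- function(atoms, d, s, is_predicted,
                                instance_id = NULL) {
  keys <- unique(atoms$key)
  aa <- atoms$aa[match(keys, atoms$key)]
  structure(list(
    instance_id = instance_id %||% paste0(s$source_id, "_", d$domain_id),
    domain_id = d$domain_id, cath_code = d$cath_code,
    topology_code = d$topology_code, protein_acc = d$protein_acc,
    source = s$source_id, method = s$method, resolution = s$resolution,
    atoms = atoms, seq = paste(aa, collapse = ""),
    n_res = length(keys), n_segments = nrow(d$segments),
    is_predicted = is_predicted, pid = NA_real_, window = NULL,
    extended_termini = NA), class = "domain_instance")
}

#' @export
print.domain_instance <- function(x, ...) {
  cat("domain_instance", x$instance_id, "—", x$n_res, "residues,",
      x$n_segments, "segment(s),",
      if (isTRUE(x$is_predicted)) "predicted" else "experimental", "\n")
  invisible(x)
}

#' Residue-level view of an instance
#'
#' @param inst a `domain_instance`.
#' @return data frame with one row per residue: `key`, `chain`, `resno`,
#'   `insert`, `aa`, `has_ca`.
#' @export
residue_table <- function(inst) {
  a <- inst$atoms
  keys <- unique(a$key)
  idx <- match(keys, a$key)
  data.frame(key = keys, chain = a$chain[idx], resno = a$resno[idx],
             insert = a$insert[idx], aa = a$aa[idx],
             has_ca = keys %in% a$key[a$elety == "CA"],
             stringsAsFactors = FALSE)
}

#' C-alpha coordinates of an instance
#'
#' @param inst a `domain_instance`.
#' @param keys optional residue keys to select (in the given order).
#' @return numeric matrix (n x 3) with residue keys as row names.
#' @export
ca_xyz <- function(inst, keys = NULL) {
  a <- inst$atoms[inst$atoms$elety == "CA", , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$key
  if (!is.null(keys)) {
    miss <- setdiff(keys, rownames(m))
    if (length(miss))
      stop_fc(paste0("residues without CA: ", paste(head(miss, 5), collapse = ", ")),
              "fc_missing_atoms")
    m <- m[keys, , drop = FALSE]
  }
  m
}

#' Write a domain instance as a PDB file
#'
#' Residue labels (chain, author number, insertion code), coordinates,
#' occupancies and B-factors are preserved so the file round-trips through
#' [read_structure()].
#'
#' @param inst a `domain_instance` (or `structure_model`).
#' @param path output path.
#' @export
write_domain_pdb <- function(inst, path) {
  a <- inst$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resid, eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Curation configuration
#'
#' Thresholds of the curation funnel: a protein must have at least
#' `min_structures_per_protein` distinct experimental source structures;
#' instances with `n_res <= min_length`, sequence identity to the reference
#' below `min_pid` percent, resolution above `max_resolution` Angstrom, or a
#' flagged extended terminus are removed. `plddt_threshold`/`plddt_fraction`
#' govern the confidence filter for predicted models.
#'
#' @param min_structures_per_protein integer, default 10.
#' @param min_pid percent, default 99.
#' @param min_length residues; instances with `n_res <= min_length` are
#'   rejected (default 10).
#' @param max_resolution Angstrom, default 3.0.
#' @param plddt_threshold per-residue confidence cutoff, default 80.
#' @param plddt_fraction required fraction above threshold, default 0.90.
#' @param terminus_window consecutive residues defining an "extended"
#'   terminus, default 5.
#' @param terminus_dev per-residue deviation cutoff in Angstrom, default 5.
#' @return object of class `curation_config`.
#' @export
curation_config <- function(min_structures_per_protein = 10, min_pid = 99,
                            min_length = 10, max_resolution = 3.0,
                            plddt_threshold = 80, plddt_fraction = 0.90,
                            terminus_window = 5, terminus_dev = 5.0) {
  cfg <- list(min_structures_per_protein = min_structures_per_protein,
              min_pid = min_pid, min_length = min_length,
              max_resolution = max_resolution,
              plddt_threshold = plddt_threshold,
              plddt_fraction = plddt_fraction,
              terminus_window = terminus_window, terminus_dev = terminus_dev)
  if (any(unlist(cfg) <= 0)) stop_fc("all thresholds must be positive",
                                     "fc_validation_error")
  structure(cfg, class = "curation_config")
}

#' Apply the curation filters to a set of domain instances
#'
#' Rules are applied in a fixed order — structure counts, length, sequence
#' identity, resolution, extended termini — and each rejected instance is
#' tagged with the first rule it fails, so rejection summaries are
#' reproducible and partition the input.
#'
#' @param instances list of `domain_instance` (experimental; `pid` and
#'   `extended_termini` populated upstream where applicable).
#' @param cfg a [curation_config()].
#' @return list with `kept` (list of instances) and `rejected` (data frame
#'   `instance_id`, `reason`).
#' @export
apply_curation <- function(instances, cfg = curation_config()) {
  if (length(instances) == 0)
    return(list(kept = list(),
                rejected = data.frame(instance_id = character(),
                                      reason = character())))
  acc <- vapply(instances, function(x) x$protein_acc, "")
  src <- vapply(instances, function(x) x$source, "")
  n_src <- tapply(src, acc, function(s) length(unique(s)))
  reason <- vapply(instances, function(inst) {
    if (n_src[[inst$protein_acc]] < cfg$min_structures_per_protein) return("counts")
    if (inst$n_res <= cfg$min_length) return("length")
    if (!is.na(inst$pid) && inst$pid < cfg$min_pid) return("pid")
    if (!is.na(inst$resolution) && inst$resolution > cfg$max_resolution)
      return("resolution")
    if (isTRUE(inst$extended_termini)) return("termini")
    ""
  }, "")
  ids <- vapply(instances, function(x) x$instance_id, "")
  list(kept = instances[reason == ""],
       rejected = data.frame(instance_id = ids[reason != ""],
                             reason = reason[reason != ""],
                             stringsAsFactors = FALSE))
}

#' Flag instances whose termini swing away from the reference
#'
#' Superposes the instance on the reference over the mapped core (terminal
#' runs that already deviate under a whole-map fit are excluded from the
#' core), then flags the instance when more than `terminus_window`
#' consecutive mapped residues at either terminus deviate by more than
#' `terminus_dev` Angstrom. Deterministic two-pass rule; a rigid-body copy of
#' the reference is never flagged.
#'
#' @param inst,ref `domain_instance` objects sharing a residue map.
#' @param map a `residue_map` between `inst` and `ref`; when `NULL`, residues
#'   are matched by identical keys.
#' @param cfg a [curation_config()] supplying `terminus_window` and
#'   `terminus_dev`.
#' @return logical flag.
#' @export
detect_extended_termini <- function(inst, ref, map = NULL,
                                    cfg = curation_config()) {
  if (is.null(map)) map <- match_by_keys(inst, ref)
  w <- cfg$terminus_window
  n <- nrow(map)
  if (n < 2 * w) {
    warning("residue map shorter than twice the terminus window; not flagged")
    return(FALSE)
  }
  a <- ca_xyz(ref, map$model_key)
  b <- ca_xyz(inst, map$inst_key)
  dev <- superpose_dev(a, b)
  p1 <- run_from_start(dev > cfg$terminus_dev)
  s1 <- run_from_start(rev(dev > cfg$terminus_dev))
  core <- seq_len(n)
  if (p1 + s1 < n - 2) core <- core[(p1 + 1):(n - s1)] else return(TRUE)
  fit <- kabsch_superpose(a[core, , drop = FALSE], b[core, , drop = FALSE])
  ball <- sweep(b, 2, fit$centroid_b) %*% fit$rotation
  ball <- sweep(ball, 2, fit$centroid_a, FUN = "+")
  dev2 <- sqrt(rowSums((a - ball)^2))
  over <- dev2 > cfg$terminus_dev
  run_from_start(over) > w || run_from_start(rev(over)) > w
}

run_from_start <- function(flags) {
  if (!length(flags) || !flags[1]) return(0L)
  r <- rle(flags)
  r$lengths[1]
}

superpose_dev <- function(a, b) {
  fit <- kabsch_superpose(a, b)
  bt <- sweep(b, 2, fit$centroid_b) %*% fit$rotation
  bt <- sweep(bt, 2, fit$centroid_a, FUN = "+")
  sqrt(rowSums((a - bt)^2))
}

# fallback map for same-labelled structures (synthetic conformers)
match_by_keys <- function(inst, ref) {
  ri <- residue_table(inst); rr <- residue_table(ref)
  common <- intersect(ri$key[ri$has_ca], rr$key[rr$has_ca])
  if (!length(common)) stop_fc("no shared residue keys", "fc_empty_map")
  structure(data.frame(inst_key = common, model_key = common,
                       inst_pos = match(common, ri$key),
                       ref_pos = match(common, rr$key),
                       stringsAsFactors = FALSE),
            class = c("residue_map", "data.frame"), pid = 100)
}

#' Confidence filter for predicted domain instances
#'
#' Keeps a predicted instance when at least `plddt_fraction` of its residues
#' have per-residue confidence (pLDDT, stored in the B-factor column) above
#' `plddt_threshold`.
#'
#' @param pred a predicted `domain_instance`.
#' @param cfg a [curation_config()].
#' @return logical flag.
#' @export
confidence_filter <- function(pred, cfg = curation_config()) {
  if (!isTRUE(pred$is_predicted))
    stop_fc("confidence_filter expects a predicted instance", "fc_validation_error")
  a <- pred$atoms[pred$atoms$elety == "CA", , drop = FALSE]
  if (nrow(a) == 0) a <- pred$atoms
  plddt <- tapply(a$b, a$key, mean)
  if (anyNA(plddt)) stop_fc("missing pLDDT values", "fc_missing_plddt")
  mean(plddt > cfg$plddt_threshold) >= cfg$plddt_fraction
}
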