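#' Specification of a synthetic single-cell dataset
#'
#' Defines the planted structure the simulator emits: negative-binomial
#' counts with disjoint pathway "program" gene blocks whose means are
#' multiplied by `program_effect` in cells of the types that activate them,
#' extra dropout zeros, and optionally a batch effect that multiplies the
#' means of a random subset of *non-program* genes per batch — so batch noise
#' perturbs gene space while the planted programs stay conserved.
#'
#' @param n_cells,n_genes matrix dimensions (defaults 2000 x 2000).
#' @param n_types number of planted cell types (default 3); type `t`
#'   activates programs `2t-1` and `2t`.
#' @param n_program_sets number of disjoint program gene blocks (default
#'   `2 * n_types`).
#' @param genes_per_program block size (default 50).
#' @param program_effect mean fold-increase on the NB mean for active
#'   programs (default 4).
#' @param baseline_mean,baseline_dispersion negative-binomial baseline mean
#'   (default 0.5) and dispersion/size (default 2).
#' @param dropout extra-zero rate (default 0.3).
#' @param batch `"none"` or `"nonprogram_shift"`.
#' @param batch_shift mean fold-change applied to shifted genes (default 2).
#' @param n_batches number of batches (default 2).
#' @param nonprogram_fraction fraction of non-program genes shifted per batch
#'   (default 0.2).
#' @param n_noise_sets extra random gene sets written to the program GMT so
#'   pathway space has realistic width (default 30).
#' @param n_distractor_signatures distractor marker signatures in the marker
#'   GMT (default 9; with 3 types this yields a 12-signature marker file).
#' @param markers_per_type marker genes per planted type signature
#'   (default 20).
#' @param seed integer seed; the bundle is fully determined by it.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 2000L, n_genes = 2000L, n_types = 3L,
                           n_program_sets = 2L * n_types,
                           genes_per_program = 50L, program_effect = 4,
                           baseline_mean = 0.5, baseline_dispersion = 2,
                           dropout = 0.3,
                           batch = c("none", "nonprogram_shift"),
                           batch_shift = 2, n_batches = 2L,
                           nonprogram_fraction = 0.2,
                           n_noise_sets = 30L, n_distractor_signatures = 9L,
                           markers_per_type = 20L, seed = 1L) {
  batch <- match.arg(batch)
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               n_types = as.integer(n_types),
               n_program_sets = as.integer(n_program_sets),
               genes_per_program = as.integer(genes_per_program),
               program_effect = program_effect, baseline_mean = baseline_mean,
               baseline_dispersion = baseline_dispersion, dropout = dropout,
               batch = batch, batch_shift = batch_shift,
               n_batches = as.integer(n_batches),
               nonprogram_fraction = nonprogram_fraction,
               n_noise_sets = as.integer(n_noise_sets),
               n_distractor_signatures = as.integer(n_distractor_signatures),
               markers_per_type = as.integer(markers_per_type),
               seed = as.integer(seed))
  if (spec$n_program_sets < spec$n_types)
    abort("need at least one program per type")
  if (spec$n_program_sets * spec$genes_per_program > spec$n_genes)
    abort("programs exceed the gene count")
  for (f in c("program_effect", "baseline_mean", "baseline_dispersion",
              "batch_shift"))
    if (spec[[f]] <= 0) abort(sprintf("`%s` must be positive", f))
  if (spec$dropout < 0 || spec$dropout >= 1) abort("`dropout` must be in [0, 1)")
  structure(spec, class = "synthetic_spec")
}

# type t activates programs 2t-1 and 2t (wrapping when fewer programs exist)
type_programs <- function(spec) {
  lapply(seq_len(spec$n_types), function(t) {
    p <- c(2L * t - 1L, 2L * t)
    unique((p - 1L) %% spec$n_program_sets + 1L)
  })
}

#' Simulate a planted single-cell dataset bundle
#'
#' Generates everything the toolkit consumes: a counts matrix, per-cell type
#' and batch labels, a program gene-set GMT (planted programs plus random
#' noise sets), a marker GMT (one signature per planted type plus
#' distractors), and the ground truth. Bit-identical for a fixed spec.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_bundle`: `counts` (genes x cells),
#'   `cell_types`, `batches`, `programs` ([gene_set_collection()]),
#'   `markers` ([gene_set_collection()]), `truth` (list).
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  with_stage_seed(spec$seed, "simulate_dataset", {
    genes <- sprintf("gene%04d", seq_len(spec$n_genes))
    cells <- sprintf("cell%04d", seq_len(spec$n_cells))
    prog_idx <- split(seq_len(spec$n_program_sets * spec$genes_per_program),
                      rep(seq_len(spec$n_program_sets),
                          each = spec$genes_per_program))
    names(prog_idx) <- sprintf("program%02d", seq_len(spec$n_program_sets))
    cell_types <- sample(rep_len(seq_len(spec$n_types), spec$n_cells))
    batches <- if (spec$batch == "none") rep(1L, spec$n_cells)
    else sample(rep_len(seq_len(spec$n_batches), spec$n_cells))
    tp <- type_programs(spec)

    mu <- matrix(spec$baseline_mean, spec$n_genes, spec$n_cells)
    for (t in seq_len(spec$n_types)) {
      active <- unlist(prog_idx[tp[[t]]], use.names = FALSE)
      mu[active, cell_types == t] <- mu[active, cell_types == t] * spec$program_effect
    }
    batch_shifted <- list()
    if (spec$batch == "nonprogram_shift") {
      nonprog <- setdiff(seq_len(spec$n_genes),
                         unlist(prog_idx, use.names = FALSE))
      for (b in seq_len(spec$n_batches)) {
        shifted <- sample(nonprog, round(spec$nonprogram_fraction * length(nonprog)))
        mu[shifted, batches == b] <- mu[shifted, batches == b] * spec$batch_shift
        batch_shifted[[b]] <- shifted
      }
    }
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = spec$baseline_dispersion),
                     spec$n_genes, spec$n_cells, dimnames = list(genes, cells))
    if (spec$dropout > 0) {
      drop <- matrix(rbinom(length(counts), 1L, spec$dropout) == 1L,
                     spec$n_genes, spec$n_cells)
      counts[drop] <- 0L
    }

    program_sets <- lapply(prog_idx, function(i) genes[i])
    noise_sets <- lapply(seq_len(spec$n_noise_sets), function(i)
      genes[sample.int(spec$n_genes, spec$genes_per_program)])
    names(noise_sets) <- sprintf("noise%02d", seq_len(spec$n_noise_sets))
    programs <- gene_set_collection(c(program_sets, noise_sets),
                                    source = "synthetic_programs")

    marker_sets <- lapply(seq_len(spec$n_types), function(t) {
      unlist(lapply(prog_idx[tp[[t]]], function(i)
        genes[i[seq_len(min(spec$markers_per_type, length(i)))]]),
        use.names = FALSE)
    })
    names(marker_sets) <- sprintf("type%d_markers", seq_len(spec$n_types))
    # distractors emulate markers of related-but-absent cell types: coherent
    # signatures drawing genes from two programs of *different* planted types
    # (gene ranges disjoint from the true signatures), so their score profile
    # is structured rather than flat noise
    prog_type <- rep(NA_integer_, spec$n_program_sets)
    for (t in seq_len(spec$n_types)) prog_type[tp[[t]]] <- t
    half <- max(1L, spec$markers_per_type %/% 2L)
    distractors <- lapply(seq_len(spec$n_distractor_signatures), function(i) {
      repeat {
        pq <- sample.int(spec$n_program_sets, 2L)
        if (!identical(prog_type[pq[1]], prog_type[pq[2]])) break
      }
      take <- function(p) {
        i_ <- prog_idx[[p]]
        lo <- min(spec$markers_per_type + 1L, length(i_))
        pool <- i_[lo:length(i_)]
        genes[sample(pool, min(half, length(pool)))]
      }
      unique(c(take(pq[1]), take(pq[2])))
    })
    names(distractors) <- sprintf("distractor%02d",
                                  seq_len(spec$n_distractor_signatures))
    markers <- gene_set_collection(c(marker_sets, distractors),
                                   source = "synthetic_markers")

    structure(list(counts = counts,
                   cell_types = setNames(cell_types, cells),
                   batches = setNames(batches, cells),
                   programs = programs, markers = markers,
                   truth = list(spec = unclass(spec),
                                type_programs = tp,
                                program_genes = lapply(prog_idx, function(i) genes[i]),
                                batch_shifted_genes = lapply(batch_shifted,
                                                             function(i) genes[i]))),
              class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d genes x %d cells, %d types, %d batches, %d program sets, %d marker signatures\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types)),
              length(unique(x$batches)), length(x$programs$sets) ,
              length(x$markers$sets)))
  invisible(x)
}

#' Simulate a toy ontology with attached gene sets
#'
#' Builds `n_branches` balanced `is_a` trees of the given depth under a
#' single root, names branches after broad biological themes, attaches a
#' random gene set to every leaf term, and optionally flags a fraction of
#' non-root terms obsolete for pruning tests.
#'
#' @param n_branches number of first-level branches (>= 2).
#' @param depth levels below the root within each branch (>= 2); each branch
#'   contains `2^depth - 1` terms (binary tree).
#' @param sets_per_leaf gene sets attached per leaf (default 1).
#' @param genes_per_set genes drawn per set (default 15).
#' @param universe gene universe to draw from.
#' @param obsolete_fraction fraction of non-root terms flagged obsolete.
#' @param seed integer seed.
#' @return A list: `graph` ([ontology_graph()], unpruned) and `collection`
#'   ([gene_set_collection()] keyed by leaf term ids).
#' @export
simulate_ontology <- function(n_branches = 2L, depth = 3L, sets_per_leaf = 1L,
                              genes_per_set = 15L,
                              universe = sprintf("gene%04d", 1:500),
                              obsolete_fraction = 0, seed = 1L) {
  if (n_branches < 2L) abort("`n_branches` must be >= 2")
  if (depth < 2L) abort("`depth` must be >= 2")
  themes <- c("immune", "metabolism", "signaling", "development", "transport",
              "stress", "cycle", "adhesion")
  with_stage_seed(seed, "simulate_ontology", {
    ids <- "ROOT:0"; names_ <- "biological process"; parent <- NA_character_
    for (b in seq_len(n_branches)) {
      theme <- themes[(b - 1L) %% length(themes) + 1L]
      # binary tree: node k has children 2k, 2k+1 (within-branch numbering)
      n_nodes <- 2L^depth - 1L
      bid <- sprintf("T:%d.%d", b, seq_len(n_nodes))
      bparent <- c("ROOT:0", bid[(2:n_nodes) %/% 2L])
      ids <- c(ids, bid)
      names_ <- c(names_, sprintf("%s term %d", theme, seq_len(n_nodes)))
      parent <- c(parent, bparent)
    }
    obsolete <- rep(FALSE, length(ids))
    if (obsolete_fraction > 0) {
      candidates <- which(ids != "ROOT:0")
      n_obs <- round(obsolete_fraction * length(candidates))
      obsolete[sample(candidates, n_obs)] <- TRUE
    }
    has_parent <- !is.na(parent)
    graph <- ontology_graph(
      tibble(id = ids, name = names_, obsolete = obsolete),
      tibble(parent = parent[has_parent], child = ids[has_parent]))
    leaves <- setdiff(ids, parent[has_parent])
    sets <- list()
    for (leaf in leaves) {
      for (s in seq_len(sets_per_leaf)) {
        id <- if (sets_per_leaf == 1L) leaf else sprintf("%s.s%d", leaf, s)
        sets[[id]] <- sample(universe, genes_per_set)
      }
    }
    nm <- setNames(names_, ids)[sub("\\.s\\d+$", "", names(sets))]
    list(graph = graph,
         collection = gene_set_collection(sets, names_ = nm,
                                          source = "synthetic_ontology"))
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the on-disk artifact set consumed by the CLI: `matrix.mtx` +
#' `features.tsv`/`barcodes.tsv`, `cell_types.tsv`, `batches.tsv`,
#' `programs.gmt`, `markers.gmt` and `truth.json`.
#'
#' @param bundle a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_mtx(bundle$counts, file.path(dir, "matrix.mtx"))
  write.table(tibble(cell_id = names(bundle$cell_types),
                     cell_type = bundle$cell_types),
              file.path(dir, "cell_types.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tibble(cell_id = names(bundle$batches), batch = bundle$batches),
              file.path(dir, "batches.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(bundle$programs, file.path(dir, "programs.gmt"))
  write_gmt(bundle$markers, file.path(dir, "markers.gmt"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
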