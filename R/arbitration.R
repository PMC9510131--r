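## Competitive-modelling arbitration across an ensemble of predicted
## structures of the same complex: classify members (complex / no complex /
## overlap artifact), cluster alternate geometries by fraction of common
## contacts (fcc), compute per-geometry frequencies over all runs, select
## the energetically best representative, and label dimer topologies.

#' Ensemble member
#'
#' One predicted structure out of a repeated-prediction ensemble.
#'
#' @param model a [structure_model()].
#' @param run_id integer run identifier.
#' @param ptm_score optional predictor confidence score; carried as
#'   metadata only, never used for selection.
#' @return object of class `ensemble_member` with `status = "unscored"`.
#' @export
ensemble_member <- function(model, run_id, ptm_score = NA_real_) {
  structure(list(model = model, run_id = as.integer(run_id),
                 ptm_score = ptm_score, dg = NULL, status = "unscored"),
            class = "ensemble_member")
}

#' Score ensemble members
#'
#' Assigns each member a status. A member is an `artifact_overlap` when the
#' fraction of residues involved in cross-group steric clashes exceeds
#' `overlap_fraction` (predictors frequently emit interpenetrating chains
#' when no defined complex exists); otherwise `no_complex` when
#' [classify_complex()] says so on the computed binding energy; otherwise
#' `complex`. The binding energy is stored on every non-artifact member.
#'
#' @param members list of [ensemble_member()]s sharing one chain naming.
#' @param group_a,group_b disjoint chain-id sets.
#' @param dg_threshold no-complex magnitude threshold, kcal/mol.
#' @param overlap_fraction clashing-residue fraction above which a member
#'   is an overlap artifact.
#' @param cutoff contact cutoff (Angstrom).
#' @param clash_tolerance vdW overlap tolerance (Angstrom).
#' @param sasa_points sphere points for SASA.
#' @return the members, with `status` and `dg` filled in.
#' @export
score_members <- function(members, group_a, group_b, dg_threshold = 3.0,
                          overlap_fraction = 0.1, cutoff = 5.5,
                          clash_tolerance = 0.4, sasa_points = 240) {
  chains0 <- sort(chain_ids(members[[1]]$model))
  for (m in members) {
    if (!identical(sort(chain_ids(m$model)), chains0)) {
      stop("inconsistent chain sets across ensemble members")
    }
  }
  lapply(members, function(m) {
    ov <- clash_residue_fraction(m$model, group_a, group_b,
                                 tolerance = clash_tolerance)
    if (ov > overlap_fraction) {
      m$status <- "artifact_overlap"
      return(m)
    }
    m$dg <- binding_energy(m$model, group_a, group_b, cutoff = cutoff,
                           sasa_points = sasa_points)
    m$status <- if (classify_complex(m$dg, threshold = dg_threshold) ==
                    "no_complex") "no_complex" else "complex"
    m
  })
}

## Residue-level interface contact set as a character vector of pair keys.
## swap = TRUE swaps the group-a / group-b orientation of each pair (used
## for the homodimer chain-relabelling ambiguity).
contact_set <- function(model, group_a, group_b, cutoff = 5.5,
                        swap = FALSE) {
  ct <- interface_contacts(model, group_a, group_b, cutoff = cutoff)$contacts
  if (nrow(ct) == 0L) return(character(0))
  a <- paste(ct$res_number_a, ct$ins_code_a, sep = ".")
  b <- paste(ct$res_number_b, ct$ins_code_b, sep = ".")
  if (swap) paste(b, a, sep = "~") else paste(a, b, sep = "~")
}

#' Fraction of common contacts between two contact sets
#'
#' fcc = |intersection| / |union|; 0 when either set is empty. The union
#' denominator (Jaccard form) keeps a geometry that strictly extends
#' another's interface (extra contacts on top of a shared core) from
#' being collapsed onto it, which the min-denominator form would do.
#'
#' @param set1,set2 character vectors of contact keys.
#' @return numeric in [0, 1].
#' @export
fcc <- function(set1, set2) {
  if (length(set1) == 0L || length(set2) == 0L) return(0)
  inter <- length(intersect(set1, set2))
  inter / (length(set1) + length(set2) - inter)
}

#' Pairwise fcc matrix of complex-status members
#'
#' For homodimers the chain labels are arbitrary, so each pair is scored
#' under both the identity and the swapped chain mapping and the better
#' similarity kept (`chain_swap = TRUE`).
#'
#' @param members list of scored members (any status; all are scored).
#' @param group_a,group_b chain groups.
#' @param cutoff contact cutoff (Angstrom).
#' @param chain_swap consider the swapped chain mapping too.
#' @return symmetric numeric matrix with run ids as dimnames.
#' @export
fcc_matrix <- function(members, group_a, group_b, cutoff = 5.5,
                       chain_swap = TRUE) {
  sets <- lapply(members, function(m)
    contact_set(m$model, group_a, group_b, cutoff = cutoff))
  sets_sw <- if (chain_swap) {
    lapply(members, function(m)
      contact_set(m$model, group_a, group_b, cutoff = cutoff, swap = TRUE))
  } else sets
  n <- length(members)
  M <- diag(1, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        s <- fcc(sets[[i]], sets[[j]])
        if (chain_swap) s <- max(s, fcc(sets[[i]], sets_sw[[j]]))
        M[i, j] <- M[j, i] <- s
      }
    }
  }
  ids <- vapply(members, `[[`, 1L, "run_id")
  dimnames(M) <- list(ids, ids)
  M
}

#' Cluster alternate geometries by contact similarity
#'
#' Single-linkage clustering of the complex-status members at an fcc
#' cutoff: two members share a geometry when their interface contact sets
#' agree on at least `similarity_cutoff` of the smaller set. Frequencies
#' are counted against all runs (not just complex-status runs). Singleton
#' clusters are flagged inconsistent and are never significant.
#'
#' @param members list of scored members (all statuses; only `complex`
#'   members are clustered).
#' @param n_runs total number of runs in the ensemble (frequency
#'   denominator); default `length(members)`.
#' @param similarity_cutoff fcc threshold for same-geometry.
#' @param group_a,group_b chain groups.
#' @param cutoff contact cutoff (Angstrom).
#' @param chain_swap see [fcc_matrix()].
#' @return list of `geometry_cluster` objects: fields `members` (run ids),
#'   `representative` (run id, most favourable dG), `frequency`,
#'   `consistent` (FALSE for singletons), `label` (`NA` until topology
#'   labelling).
#' @export
cluster_geometries <- function(members, n_runs = length(members),
                               similarity_cutoff = 0.5,
                               group_a = "A", group_b = "B", cutoff = 5.5,
                               chain_swap = TRUE) {
  cx <- Filter(function(m) m$status == "complex", members)
  if (length(cx) == 0L) return(list())
  M <- fcc_matrix(cx, group_a, group_b, cutoff = cutoff,
                  chain_swap = chain_swap)
  ## connected components of the >= cutoff graph = single linkage
  n <- length(cx)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(M[i, ] >= similarity_cutoff)
      new <- min(comp[nb], comp[i])
      upd <- nb[comp[nb] != new]
      if (length(upd) > 0L || comp[i] != new) {
        comp[c(i, upd)] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ids <- vapply(cx, `[[`, 1L, "run_id")
  clusters <- lapply(sort(unique(comp)), function(cc) {
    sel <- which(comp == cc)
    runs <- sort(ids[sel])
    structure(list(
      members = runs,
      representative = select_best(runs, members),
      frequency = length(sel) / n_runs,
      consistent = length(sel) > 1L,
      label = NA_character_), class = "geometry_cluster")
  })
  ## largest geometry first
  clusters[order(-vapply(clusters, `[[`, 0, "frequency"),
                 vapply(clusters, function(cl) cl$members[1], 0L))]
}

#' @export
print.geometry_cluster <- function(x, ...) {
  cat(sprintf("<geometry_cluster> %d member(s), frequency %.2f, representative run %d%s\n",
              length(x$members), x$frequency, x$representative,
              if (!x$consistent) " [inconsistent singleton]" else ""))
  invisible(x)
}

#' Select the best member of a cluster by binding affinity
#'
#' The retained structure is the one with the most favourable (most
#' negative) computed binding energy; predictor confidence scores are
#' never consulted. Ties break to the lowest run id.
#'
#' @param cluster_runs integer run ids of the cluster, or a
#'   `geometry_cluster`.
#' @param members the scored ensemble (must carry `dg` for those runs).
#' @return the representative run id.
#' @export
select_best <- function(cluster_runs, members) {
  if (inherits(cluster_runs, "geometry_cluster")) {
    cluster_runs <- cluster_runs$members
  }
  stopifnot(length(cluster_runs) > 0L)
  ids <- vapply(members, `[[`, 1L, "run_id")
  sel <- members[match(cluster_runs, ids)]
  dg <- vapply(sel, function(m) {
    if (is.null(m$dg)) stop("member ", m$run_id, " has no binding energy")
    m$dg$dg
  }, 0)
  runs <- vapply(sel, `[[`, 1L, "run_id")
  ord <- order(dg, runs)
  runs[ord[1]]
}

#' Arbitrate among alternate predicted conformations
#'
#' Full pipeline: score members, cluster complex-status geometries,
#' determine which geometries are significant (frequency at least
#' `min_frequency` over all runs, singletons excluded), and return a
#' verdict: `no_complex` when no geometry is significant,
#' `single_geometry`, or `alternate_geometries`.
#'
#' @param members list of [ensemble_member()]s.
#' @param group_a,group_b disjoint chain-id sets.
#' @param dg_threshold,overlap_fraction see [score_members()].
#' @param min_frequency significance threshold on cluster frequency.
#' @param similarity_cutoff fcc threshold for same-geometry.
#' @param cutoff contact cutoff (Angstrom).
#' @param sasa_points sphere points for SASA.
#' @return object of class `arbitration_report`: `n_runs`, `members`
#'   (scored), `clusters`, `significant` (indices into `clusters`),
#'   `status_fractions`, `verdict`.
#' @export
arbitrate <- function(members, group_a, group_b, dg_threshold = 3.0,
                      min_frequency = 0.2, similarity_cutoff = 0.5,
                      overlap_fraction = 0.1, cutoff = 5.5,
                      sasa_points = 240) {
  n_runs <- length(members)
  scored <- score_members(members, group_a, group_b,
                          dg_threshold = dg_threshold,
                          overlap_fraction = overlap_fraction,
                          cutoff = cutoff, sasa_points = sasa_points)
  clusters <- cluster_geometries(scored, n_runs = n_runs,
                                 similarity_cutoff = similarity_cutoff,
                                 group_a = group_a, group_b = group_b,
                                 cutoff = cutoff)
  sig <- which(vapply(clusters, function(cl)
    cl$consistent && cl$frequency >= min_frequency, TRUE))
  status <- vapply(scored, `[[`, "", "status")
  verdict <- if (length(sig) == 0L) "no_complex"
             else if (length(sig) == 1L) "single_geometry"
             else "alternate_geometries"
  structure(list(
    n_runs = n_runs, members = scored, clusters = clusters,
    significant = sig,
    status_fractions = table(factor(status, levels = c(
      "complex", "no_complex", "artifact_overlap", "unscored"))) / n_runs,
    verdict = verdict), class = "arbitration_report")
}

#' @export
print.arbitration_report <- function(x, ...) {
  cat(sprintf("<arbitration_report> %d runs, %d geometr%s, verdict: %s\n",
              x$n_runs, length(x$clusters),
              if (length(x$clusters) == 1) "y" else "ies", x$verdict))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: freq %.2f, rep run %d%s%s\n", i,
                cl$frequency, cl$representative,
                if (i %in% x$significant) " [significant]" else "",
                if (!is.na(cl$label)) paste0(" label=", cl$label) else ""))
  }
  invisible(x)
}

## Residue-pair contact count between two domain ranges (same or
## different chains).
region_contact_count <- function(model, spec_a, spec_b, cutoff = 5.5) {
  at <- model$atoms[geometry_mask(model$atoms), , drop = FALSE]
  A <- at[range_mask(at, spec_a$chain_id, spec_a$start, spec_a$end), ,
          drop = FALSE]
  B <- at[range_mask(at, spec_b$chain_id, spec_b$start, spec_b$end), ,
          drop = FALSE]
  if (nrow(A) == 0L || nrow(B) == 0L) return(0L)
  pairs <- close_atom_pairs(as.matrix(A[, c("x", "y", "z")]),
                            as.matrix(B[, c("x", "y", "z")]), cutoff)
  if (nrow(pairs) == 0L) return(0L)
  length(unique(paste(residue_key(A)[pairs[, 1]],
                      residue_key(B)[pairs[, 2]], sep = "~")))
}

#' Classify the domain topology of a two-chain multidomain dimer
#'
#' Each chain carries one mobile domain (e.g. the FMN domain) and the other
#' listed domains are candidate partners (e.g. the FAD or P450 domains of
#' both chains). Each mobile domain is assigned the partner domain with the
#' largest residue-contact count. When both mobile domains bind a
#' same-chain partner the topology is intrachain (`closed` for FAD-class
#' partners, `cis` for P450-class); when both bind the opposite chain it is
#' interchain (`crossed` / `trans`); mixed assignments or no contacts give
#' `undetermined`.
#'
#' @param model a two-chain [structure_model()].
#' @param domains list of [domain_spec()]s covering both chains.
#' @param mobile label of the mobile domain in `domains` (default
#'   `"FMNd"`).
#' @param cutoff contact cutoff (Angstrom).
#' @param labels optional `c(intra = ..., inter = ...)` label override;
#'   by default P450-class partners give `c("cis", "trans")` and anything
#'   else `c("closed", "crossed")`.
#' @return one of `"cis"`, `"trans"`, `"closed"`, `"crossed"`,
#'   `"undetermined"`.
#' @export
classify_topology <- function(model, domains, mobile = "FMNd",
                              cutoff = 5.5, labels = NULL) {
  if (length(chain_ids(model)) != 2L) {
    stop("topology classification requires exactly two chains")
  }
  labs <- vapply(domains, `[[`, "", "label")
  mob <- domains[labs == mobile]
  partners <- domains[labs != mobile]
  if (length(mob) != 2L) {
    stop("need the mobile domain '", mobile, "' on both chains")
  }
  if (length(partners) == 0L) stop("no partner domain specs given")
  if (is.null(labels)) {
    plabs <- unique(vapply(partners, `[[`, "", "label"))
    labels <- if (all(grepl("P450", plabs, ignore.case = TRUE))) {
      c(intra = "cis", inter = "trans")
    } else {
      c(intra = "closed", inter = "crossed")
    }
  }
  assignment <- vapply(mob, function(ms) {
    counts <- vapply(partners, function(ps)
      region_contact_count(model, ms, ps, cutoff = cutoff), 0L)
    if (all(counts == 0L)) return(NA_character_)
    best <- partners[[which.max(counts)]]
    if (best$chain_id == ms$chain_id) "intra" else "inter"
  }, "")
  if (anyNA(assignment) || length(unique(assignment)) != 1L) {
    return("undetermined")
  }
  unname(labels[assignment[1]])
}
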