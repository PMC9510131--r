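## Interfacial residue-residue contacts between two chain groups.
## A residue pair is a contact when any heavy-atom pair across the groups
## lies within the cutoff (5.5 A, the convention of the contact-based
## binding-affinity model). Contacts are classified by the character
## (charged / polar / apolar) of the two residues.

#' Interfacial contact counts
#'
#' @param contacts data.frame of contacts as returned by
#'   [interface_contacts()], or `NULL` for all-zero counts.
#' @return object of class `contact_counts` with fields `ic_cc`, `ic_cp`,
#'   `ic_ca`, `ic_pp`, `ic_pa`, `ic_aa` (charged/charged, charged/polar,
#'   charged/apolar, polar/polar, polar/apolar, apolar/apolar).
#' @export
contact_counts <- function(contacts = NULL) {
  lv <- c("charged/charged", "charged/polar", "charged/apolar",
          "polar/polar", "polar/apolar", "apolar/apolar")
  tab <- if (is.null(contacts) || nrow(contacts) == 0L) {
    stats::setNames(rep(0L, 6L), lv)
  } else {
    table(factor(contacts$class_pair, levels = lv))
  }
  out <- list(ic_cc = as.integer(tab["charged/charged"]),
              ic_cp = as.integer(tab["charged/polar"]),
              ic_ca = as.integer(tab["charged/apolar"]),
              ic_pp = as.integer(tab["polar/polar"]),
              ic_pa = as.integer(tab["polar/apolar"]),
              ic_aa = as.integer(tab["apolar/apolar"]))
  class(out) <- "contact_counts"
  out
}

#' @export
print.contact_counts <- function(x, ...) {
  cat(sprintf(
    "<contact_counts> cc %d, cp %d, ca %d, pp %d, pa %d, aa %d (total %d)\n",
    x$ic_cc, x$ic_cp, x$ic_ca, x$ic_pp, x$ic_pa, x$ic_aa,
    x$ic_cc + x$ic_cp + x$ic_ca + x$ic_pp + x$ic_pa + x$ic_aa))
  invisible(x)
}

class_pair_label <- function(class_a, class_b) {
  ord <- c(charged = 1L, polar = 2L, apolar = 3L)
  a <- ord[class_a]; b <- ord[class_b]
  lo <- pmin(a, b); hi <- pmax(a, b)
  nm <- names(ord)
  ifelse(is.na(lo) | is.na(hi), NA_character_,
         paste(nm[lo], nm[hi], sep = "/"))
}

#' Interfacial contacts between two chain groups
#'
#' @param model a [structure_model()] holding both groups.
#' @param group_a,group_b disjoint character vectors of chain ids.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param include_hetero include heteroatom residues.
#' @return list with `contacts` (data.frame: chain_a, res_number_a,
#'   ins_code_a, res_name_a, chain_b, res_number_b, ins_code_b, res_name_b,
#'   distance, class_pair) and `counts` (a [contact_counts()]). Symmetric
#'   in the group order up to pair orientation.
#' @export
interface_contacts <- function(model, group_a, group_b, cutoff = 5.5,
                               include_hetero = FALSE) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both chain groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("chain groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  }
  a <- model$atoms[geometry_mask(model$atoms, include_hetero), , drop = FALSE]
  A <- a[a$chain %in% group_a, , drop = FALSE]
  B <- a[a$chain %in% group_b, , drop = FALSE]
  empty <- data.frame(chain_a = character(0), res_number_a = integer(0),
                      ins_code_a = character(0), res_name_a = character(0),
                      chain_b = character(0), res_number_b = integer(0),
                      ins_code_b = character(0), res_name_b = character(0),
                      distance = numeric(0), class_pair = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    return(list(contacts = empty, counts = contact_counts(NULL)))
  }
  xa <- as.matrix(A[, c("x", "y", "z")])
  xb <- as.matrix(B[, c("x", "y", "z")])
  pairs <- close_atom_pairs(xa, xb, cutoff)
  if (nrow(pairs) == 0L) {
    return(list(contacts = empty, counts = contact_counts(NULL)))
  }
  ka <- residue_key(A)[pairs[, 1]]
  kb <- residue_key(B)[pairs[, 2]]
  rk <- paste(ka, kb, sep = "~")
  ## minimum heavy-atom distance per residue pair
  o <- order(rk, pairs[, 3])
  first <- !duplicated(rk[o])
  ia <- pairs[o, 1][first]; ib <- pairs[o, 2][first]
  d <- pairs[o, 3][first]
  contacts <- data.frame(
    chain_a = A$chain[ia], res_number_a = A$res_number[ia],
    ins_code_a = A$ins_code[ia], res_name_a = A$res_name[ia],
    chain_b = B$chain[ib], res_number_b = B$res_number[ib],
    ins_code_b = B$ins_code[ib], res_name_b = B$res_name[ib],
    distance = d,
    stringsAsFactors = FALSE)
  contacts$class_pair <- class_pair_label(residue_class(contacts$res_name_a),
                                          residue_class(contacts$res_name_b))
  ord <- order(contacts$chain_a, contacts$res_number_a,
               contacts$chain_b, contacts$res_number_b)
  contacts <- contacts[ord, , drop = FALSE]
  rownames(contacts) <- NULL
  list(contacts = contacts, counts = contact_counts(contacts))
}

## All cross-set atom pairs within cutoff. Blocked distance computation;
## returns matrix with columns (i, j, distance).
close_atom_pairs <- function(xa, xb, cutoff) {
  block <- max(1L, floor(2e6 / max(1L, nrow(xb))))
  out <- vector("list", ceiling(nrow(xa) / block))
  k <- 0L
  bb2 <- rowSums(xb^2)
  for (s in seq(1L, nrow(xa), by = block)) {
    e <- min(s + block - 1L, nrow(xa))
    xs <- xa[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xs^2), bb2, `+`) - 2 * xs %*% t(xb)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      k <- k + 1L
      out[[k]] <- cbind(hit[, 1] + s - 1L, hit[, 2],
                        sqrt(pmax(0, d2[hit])))
    }
  }
  if (k == 0L) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, out[seq_len(k)])
}
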