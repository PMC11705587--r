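#' Gate nodes and gate trees
#'
#' A gate tree is a rooted hierarchy of threshold predicates over marker
#' abundances and scatter channels.  Each node carries a predicate — a
#' set of threshold terms combined with `all` (conjunction, the default)
#' or `any` — an optional terminal population name, a `target` flag
#' marking the primary populations, and a `parallel` flag for
#' confirmatory or sub-state gates that overlap their siblings (memory T
#' subsets, mature NK, CD206/CX3CR1 confirmation) and are therefore
#' excluded from the partition bookkeeping.
#'
#' @param name gate identifier (unique).
#' @param parent parent gate identifier, or `NA` for the root.
#' @param terms list of terms from [gate_term()].
#' @param combine `"all"` or `"any"`.
#' @param population terminal population name, or `NA`.
#' @param target logical: is this one of the primary target populations?
#' @param parallel logical: overlapping side gate, excluded from
#'   frequency-of-parent conservation.
#' @return A `gate_node` list.
#' @export
gate_node <- function(name, parent, terms = list(), combine = c("all", "any"),
                      population = NA_character_, target = FALSE,
                      parallel = FALSE) {
  combine <- match.arg(combine)
  structure(list(name = name, parent = parent, terms = terms,
                 combine = combine, population = population,
                 target = target, parallel = parallel),
            class = "gate_node")
}

#' @rdname gate_node
#' @param channel marker name or scatter channel (`"FSC-A"`, `"SSC-A"`,
#'   `"FSC-ratio"` for FSC-H/FSC-A).
#' @param op `">"` or `"<"`.
#' @param ref threshold reference name (defaults to the channel name);
#'   distinct references on the same channel may resolve to distinct
#'   values.
#' @export
gate_term <- function(channel, op = c(">", "<"), ref = channel) {
  op <- match.arg(op)
  list(channel = channel, op = op, ref = ref)
}

#' The murine lung gating hierarchy
#'
#' Builds the complete declarative gate tree used for lung
#' immunophenotyping: debris exclusion (FSC-A), singlets (FSC-H/FSC-A
#' ratio), live cells (viability dye negative), CD45+ leukocytes, then
#' Ly6G+ neutrophils; the myeloid branch (CD11b+ or CD11c+) with SSC-low
#' monocytes split into inflammatory (Ly6C+) and resident (CD11c+)
#' subsets, CD64+ macrophages split into alveolar (CD11c+) and
#' interstitial (CD11c-CD11b+), CD64-CD24+ eosinophils (CD11b+ MHCII-)
#' and dendritic cells (cDC1 CD103+CD11b-, cDC2 CD11b+CD103-), and
#' CD64-CD24- plasmacytoid DCs (CD11c+Ly6C+); and the lymphoid branch
#' (CD11b-CD11c-) with CD19+ B cells, CD3+ T cells (CD8+ cytotoxic, CD4+
#' helper, CD4+CD25+CD127low regulatory, each with CD44/CD62L memory
#' sub-states), and the CD3-CD19- innate compartment: CD335+CD127- NK
#' (with the CD11b+KLRG-1+CD122+ mature sub-state), CD335+CD127+ ILC1,
#' and CD335-CD127+ cells split into ILC2 (CD25+) and ILC3
#' (CD25-KLRG-1-).  CD206/CX3CR1 are carried as optional confirmatory
#' side gates for the macrophage subsets, not on the primary path.
#'
#' Thresholds are named references, resolved later by
#' [derive_thresholds()]; none is hard-coded.  The CD127 cut used for
#' Tregs and the one used for ILCs are distinct references.
#'
#' @return An object of class `gate_tree`.
#' @export
build_lung_gate_tree <- function() {
  N <- gate_node; Tm <- gate_term
  nodes <- list(
    N("root", NA_character_),
    N("nondebris", "root", list(Tm("FSC-A", ">", "FSC.debris"))),
    N("singlets", "nondebris", list(Tm("FSC-ratio", ">", "singlet.ratio"))),
    N("live", "singlets", list(Tm("Viability", "<", "Viability"))),
    N("leukocytes", "live", list(Tm("CD45", ">", "CD45"))),
    N("neutrophil", "leukocytes", list(Tm("Ly6G", ">", "Ly6G")),
      population = "Neutrophil", target = TRUE),
    N("nonneut", "leukocytes", list(Tm("Ly6G", "<", "Ly6G"))),
    N("myeloid", "nonneut",
      list(Tm("CD11b", ">", "CD11b"), Tm("CD11c", ">", "CD11c")),
      combine = "any"),
    N("monocytes", "myeloid", list(Tm("SSC-A", "<", "SSC.myeloid"))),
    N("mono_inflammatory", "monocytes", list(Tm("Ly6C", ">", "Ly6C")),
      population = "Inflammatory monocyte", target = TRUE),
    N("mono_resident", "monocytes",
      list(Tm("Ly6C", "<", "Ly6C"), Tm("CD11c", ">", "CD11c")),
      population = "Resident monocyte", target = TRUE),
    N("intermediary2", "myeloid", list(Tm("SSC-A", ">", "SSC.myeloid"))),
    N("macrophages", "intermediary2", list(Tm("CD64", ">", "CD64"))),
    N("amo", "macrophages", list(Tm("CD11c", ">", "CD11c")),
      population = "Alveolar macrophage", target = TRUE),
    N("imo", "macrophages",
      list(Tm("CD11c", "<", "CD11c"), Tm("CD11b", ">", "CD11b")),
      population = "Interstitial macrophage", target = TRUE),
    N("amo_cd206", "amo", list(Tm("CD206", ">", "CD206")), parallel = TRUE),
    N("imo_cx3cr1", "imo", list(Tm("CX3CR1", ">", "CX3CR1")), parallel = TRUE),
    N("cd24pos", "intermediary2",
      list(Tm("CD64", "<", "CD64"), Tm("CD24", ">", "CD24"))),
    N("eosinophil", "cd24pos",
      list(Tm("CD11b", ">", "CD11b"), Tm("MHCII", "<", "MHCII")),
      population = "Eosinophil", target = TRUE),
    N("dc", "cd24pos", list(Tm("MHCII", ">", "MHCII"))),
    N("cdc1", "dc", list(Tm("CD103", ">", "CD103"), Tm("CD11b", "<", "CD11b")),
      population = "cDC1", target = TRUE),
    N("cdc2", "dc", list(Tm("CD11b", ">", "CD11b"), Tm("CD103", "<", "CD103")),
      population = "cDC2", target = TRUE),
    N("cd24neg", "intermediary2",
      list(Tm("CD64", "<", "CD64"), Tm("CD24", "<", "CD24"))),
    N("pdc", "cd24neg", list(Tm("CD11c", ">", "CD11c"), Tm("Ly6C", ">", "Ly6C")),
      population = "pDC", target = TRUE),
    N("lymphoid", "nonneut",
      list(Tm("CD11b", "<", "CD11b"), Tm("CD11c", "<", "CD11c"))),
    N("bcell", "lymphoid", list(Tm("CD19", ">", "CD19"), Tm("CD3", "<", "CD3")),
      population = "B cell", target = TRUE),
    N("tcell", "lymphoid", list(Tm("CD3", ">", "CD3"), Tm("CD19", "<", "CD19"))),
    N("ctl", "tcell", list(Tm("CD8", ">", "CD8"), Tm("CD4", "<", "CD4")),
      population = "Cytotoxic T", target = TRUE),
    N("t8_eff", "ctl", list(Tm("CD44", ">", "CD44"), Tm("CD62L", "<", "CD62L")),
      population = "CD8 T effector", parallel = TRUE),
    N("t8_cm", "ctl", list(Tm("CD44", ">", "CD44"), Tm("CD62L", ">", "CD62L")),
      population = "CD8 T central memory", parallel = TRUE),
    N("t8_naive", "ctl", list(Tm("CD44", "<", "CD44"), Tm("CD62L", ">", "CD62L")),
      population = "CD8 T naive", parallel = TRUE),
    N("thelper", "tcell", list(Tm("CD4", ">", "CD4"), Tm("CD8", "<", "CD8")),
      population = "T helper", target = TRUE),
    N("treg", "thelper",
      list(Tm("CD25", ">", "CD25"), Tm("CD127", "<", "CD127.treg")),
      population = "Treg", target = TRUE),
    N("t4_eff", "thelper",
      list(Tm("CD44", ">", "CD44"), Tm("CD62L", "<", "CD62L")),
      population = "CD4 T effector", parallel = TRUE),
    N("t4_cm", "thelper",
      list(Tm("CD44", ">", "CD44"), Tm("CD62L", ">", "CD62L")),
      population = "CD4 T central memory", parallel = TRUE),
    N("t4_naive", "thelper",
      list(Tm("CD44", "<", "CD44"), Tm("CD62L", ">", "CD62L")),
      population = "CD4 T naive", parallel = TRUE),
    N("dn", "lymphoid", list(Tm("CD3", "<", "CD3"), Tm("CD19", "<", "CD19"))),
    N("cd335pos", "dn", list(Tm("CD335", ">", "CD335"))),
    N("nk", "cd335pos", list(Tm("CD127", "<", "CD127.ilc")),
      population = "NK", target = TRUE),
    N("nk_mature", "nk",
      list(Tm("CD11b", ">", "CD11b"), Tm("KLRG-1", ">", "KLRG-1"),
           Tm("CD122", ">", "CD122")),
      population = "Mature NK", parallel = TRUE),
    N("ilc1", "cd335pos", list(Tm("CD127", ">", "CD127.ilc")),
      population = "ILC1", target = TRUE),
    N("ilc_gate", "dn",
      list(Tm("CD335", "<", "CD335"), Tm("CD127", ">", "CD127.ilc"))),
    N("ilc2", "ilc_gate", list(Tm("CD25", ">", "CD25")),
      population = "ILC2", target = TRUE),
    N("ilc3", "ilc_gate",
      list(Tm("CD25", "<", "CD25"), Tm("KLRG-1", "<", "KLRG-1")),
      population = "ILC3", target = TRUE))
  gate_tree(nodes, version = "lung-v1")
}

#' @rdname gate_node
#' @param nodes list of `gate_node`s forming a rooted tree.
#' @param thresholds named numeric map (raw channel scale); usually
#'   filled in by [derive_thresholds()].
#' @param version free-form version tag.
#' @export
gate_tree <- function(nodes, thresholds = numeric(), version = "v1") {
  nm <- vapply(nodes, function(n) n$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate gate names")
  parents <- vapply(nodes, function(n) n$parent, character(1))
  roots <- which(is.na(parents))
  if (length(roots) != 1) stop("tree must have exactly one root")
  if (!all(parents[-roots] %in% nm)) stop("unknown parent gate(s)")
  ## depth-order the nodes and reject cycles
  depth <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  depth[roots] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      d <- depth[parents[i]]
      if (!is.na(d)) { depth[i] <- d + 1L; progressed <- TRUE }
    }
    if (!progressed) stop("gate tree contains a cycle")
  }
  nodes <- nodes[order(depth)]
  pops <- stats::setNames(
    vapply(nodes, function(n) n$population, character(1)),
    vapply(nodes, function(n) n$name, character(1)))
  pops <- pops[!is.na(pops)]
  if (anyDuplicated(pops)) stop("terminal population names must be unique")
  structure(list(nodes = nodes, thresholds = thresholds, version = version),
            class = "gate_tree")
}

#' @export
print.gate_tree <- function(x, ...) {
  tg <- sum(vapply(x$nodes, function(n) isTRUE(n$target), logical(1)))
  cat("<gate_tree> ", x$version, ": ", length(x$nodes), " gates, ",
      tg, " target populations, ",
      length(x$thresholds), " resolved thresholds\n", sep = "")
  invisible(x)
}

#' Target populations and referenced markers of a gate tree
#'
#' `gate_targets()` lists the terminal target population names.
#' `gate_markers()` lists the distinct marker channels referenced by the
#' tree, optionally dropping scatter channels and an exclusion set.
#'
#' @param tree a [gate_tree()].
#' @param exclude marker names to drop from the count.
#' @return Character vector.
#' @export
gate_targets <- function(tree) {
  unlist(lapply(tree$nodes, function(n)
    if (isTRUE(n$target) && !is.na(n$population)) n$population))
}

#' @rdname gate_targets
#' @export
gate_markers <- function(tree, exclude = character()) {
  ch <- unique(unlist(lapply(tree$nodes, function(n)
    vapply(n$terms, function(t) t$channel, character(1)))))
  setdiff(ch, c(scatter_channels(), "FSC-ratio", exclude))
}

## references used by the tree: ref name -> channel
.tree_refs <- function(tree) {
  terms <- do.call(rbind, lapply(tree$nodes, function(n)
    if (length(n$terms))
      data.frame(channel = vapply(n$terms, `[[`, "", "channel"),
                 ref = vapply(n$terms, `[[`, "", "ref"))))
  unique(terms)
}

## lower mode of a sample: smallest local maximum of its kernel density
## above `above` (bumps under 5% of the global peak are ignored as
## noise; spillover spread can throw spurious bumps at strongly
## negative abundances, which a gate can never sit below)
.lower_mode <- function(x, above = -Inf) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, n = 512)
  y <- d$y
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  loc <- loc[y[loc] >= 0.05 * max(y) & d$x[loc] > above]
  if (!length(loc)) loc <- which.max(y)
  d$x[min(loc)]
}

## place a threshold between a negative and a positive reference sample
## (in transformed space): midpoint between the negative upper quantile
## and the lower positive mode.  Heavy spillover-spread tails can push
## the negative quantile past the positive mode, so the negative bound
## is capped at the midpoint of negative median and positive mode; the
## channel is unresolvable when the positive mode does not exceed the
## negative median.
.place_threshold <- function(neg, pos, neg_quantile) {
  nm <- stats::median(neg)
  pm <- .lower_mode(pos, above = nm)
  ## unresolvable: the positive mode does not clear the negative median
  ## by a meaningful fraction of the positives' own spread (identical
  ## distributions land here up to density-grid jitter)
  if (pm <= nm + 0.25 * robust_sd(pos))
    return(list(value = NA_real_, flag = "unresolved"))
  nq <- min(stats::quantile(neg, neg_quantile, names = FALSE),
            (nm + pm) / 2)
  list(value = (nq + pm) / 2, flag = "ok")
}

#' Derive gate thresholds from reference data
#'
#' Resolves every threshold reference of the tree from a labelled
#' reference sample.  For marker references, negative reference events
#' are those of populations at expression level `neg`/`low` and positive
#' events those at `pos`/`hi`; in arcsinh-transformed space the threshold
#' is the midpoint between the upper `neg_quantile` of the negatives and
#' the lower density mode of the positives, then mapped back to the raw
#' scale (so gating is invariant under any strictly monotone channel
#' transform applied jointly to channel and threshold).  The viability
#' threshold separates live from dead reference events the same way; the
#' monocyte SSC-A cut separates the monocyte scatter stratum from the
#' rest of the myeloid branch; the debris cut is a fixed fraction of the
#' median FSC-A, and the singlet ratio cut is a configurable constant.
#'
#' References with no positive events resolve one-sided (just above the
#' negative distribution, flagged `"one_sided"`); references whose
#' negative and positive distributions are not separated are flagged
#' unresolved and reported — applying a tree with unresolved thresholds
#' is an error.
#'
#' @param tree a [gate_tree()].
#' @param unmixed an [unmix()] result for the reference events.
#' @param events the reference [event_table()] (provides scatter, truth
#'   labels and the live/dead flag).
#' @param profiles the [population_profile()] list that generated (or
#'   describes) the reference.
#' @param panel a [panel_config()].
#' @param cofactor arcsinh cofactor for the marker transform.
#' @param neg_quantile upper quantile of the negative reference.
#' @param singlet_ratio FSC-H/FSC-A cut for the singlet gate.
#' @param debris_fraction debris cut as a fraction of median FSC-A.
#' @return The tree with `thresholds` filled (raw channel scale) and an
#'   attribute `"flags"` (named character: `"ok"`, `"one_sided"` or
#'   `"unresolved"`).
#' @export
derive_thresholds <- function(tree, unmixed, events, profiles,
                              panel = default_lung_panel(), cofactor = 5,
                              neg_quantile = 0.995, singlet_ratio = 0.75,
                              debris_fraction = 0.25) {
  refs <- .tree_refs(tree)
  mk <- marker_matrix(unmixed, panel)
  labels <- events$truth_labels
  if (is.null(labels)) stop("reference events must carry truth labels")
  pnames <- vapply(profiles, function(p) p$name, character(1))
  lev_of <- function(marker)
    stats::setNames(vapply(profiles, function(p)
      p$marker_levels[[marker]] %||% "neg", character(1)), pnames)
  tf <- function(x) asinh(x / cofactor)
  itf <- function(y) sinh(y) * cofactor
  thr <- stats::setNames(numeric(nrow(refs)), refs$ref)
  flags <- stats::setNames(rep("ok", nrow(refs)), refs$ref)

  ## populations whose scatter stratum defines the monocyte SSC cut
  mono_pops <- intersect(c("Inflammatory monocyte", "Resident monocyte"),
                         pnames)

  for (i in seq_len(nrow(refs))) {
    ref <- refs$ref[i]; ch <- refs$channel[i]
    if (ref == "FSC.debris") {
      thr[ref] <- debris_fraction * stats::median(events$scatter[["FSC-A"]])
    } else if (ref == "singlet.ratio") {
      thr[ref] <- singlet_ratio
    } else if (ref == "SSC.myeloid") {
      myeloid <- pnames[vapply(profiles, function(p)
        any(p$marker_levels[c("CD11b", "CD11c")] %in% c("pos", "hi")),
        logical(1))]
      neg <- events$scatter[["SSC-A"]][labels %in% mono_pops]
      pos <- events$scatter[["SSC-A"]][labels %in% setdiff(myeloid, mono_pops)]
      if (!length(neg) || !length(pos)) { flags[ref] <- "unresolved"; next }
      pl <- .place_threshold(neg, pos, neg_quantile)
      thr[ref] <- pl$value
      flags[ref] <- pl$flag
    } else if (ch == "Viability") {
      if (is.null(events$alive)) { flags[ref] <- "unresolved"; next }
      neg <- tf(mk[events$alive, ch])
      pos <- tf(mk[!events$alive, ch])
      if (!length(pos)) {                    # nothing dead: one-sided gate
        thr[ref] <- itf(stats::quantile(neg, neg_quantile, names = FALSE) + 1)
        flags[ref] <- "one_sided"
      } else {
        pl <- .place_threshold(neg, pos, neg_quantile)
        thr[ref] <- itf(pl$value)
        flags[ref] <- pl$flag
      }
    } else {
      levels <- lev_of(ch)
      neg <- tf(mk[labels %in% pnames[levels %in% c("neg", "low")], ch])
      pos <- tf(mk[labels %in% pnames[levels %in% c("pos", "hi")], ch])
      if (!length(neg) && !length(pos)) { flags[ref] <- "unresolved"; next }
      if (!length(neg)) {
        ## marker positive on every reference population (e.g. CD45):
        ## one-sided gate just below the positive distribution
        thr[ref] <- itf(stats::quantile(pos, 1 - neg_quantile,
                                        names = FALSE) - 0.5)
        flags[ref] <- "one_sided"
        next
      }
      if (!length(pos)) {
        thr[ref] <- itf(stats::quantile(neg, neg_quantile, names = FALSE) + 1)
        flags[ref] <- "one_sided"
      } else {
        pl <- .place_threshold(neg, pos, neg_quantile)
        thr[ref] <- itf(pl$value)
        flags[ref] <- pl$flag
      }
    }
  }
  if (any(flags == "unresolved"))
    warning("unresolved threshold(s): ",
            paste(names(flags)[flags == "unresolved"], collapse = ", "))
  tree$thresholds <- thr
  attr(tree, "flags") <- flags
  tree
}

#' Marker abundance matrix of an unmixing result
#'
#' Renames the panel fluorochrome columns of an unmixed abundance matrix
#' to their marker names (AF columns are dropped).
#'
#' @param unmixed an [unmix()] result (or abundance matrix with
#'   fluorochrome column names).
#' @param panel a [panel_config()].
#' @return Numeric events x markers matrix.
#' @export
marker_matrix <- function(unmixed, panel) {
  ab <- if (inherits(unmixed, "unmix_result")) unmixed$abundances
        else as.matrix(unmixed)
  fl <- intersect(colnames(ab), panel$entries$fluorochrome)
  m <- ab[, fl, drop = FALSE]
  colnames(m) <- fluor_to_marker(panel, fl)
  m
}

#' Apply a gate tree to unmixed events
#'
#' Each event descends the tree; its label is the population of the
#' deepest target gate it reaches.  Events that fail every child
#' predicate at a branch (and never reached a terminal population) are
#' labelled `"<deepest gate>/unassigned"`.  The frequency table reports,
#' per gate, the event count and the frequency of the parent gate;
#' parallel (overlapping) side gates are included in the table but do
#' not enter the parent/children conservation.
#'
#' @param unmixed an [unmix()] result for the events.
#' @param events the [event_table()] (provides scatter channels).
#' @param tree a [gate_tree()] with resolved thresholds.
#' @param panel a [panel_config()].
#' @return An object of class `gating_result`: `labels` (per event),
#'   `frequency` (data.frame population/parent/count/frequency-of-parent)
#'   and `membership` (events x gates logical matrix).
#' @export
apply_gates <- function(unmixed, events, tree, panel = default_lung_panel()) {
  refs <- .tree_refs(tree)
  missing <- setdiff(refs$ref, names(tree$thresholds))
  if (length(missing))
    stop("unresolved threshold reference(s): ",
         paste(missing, collapse = ", "))
  flags <- attr(tree, "flags")
  bad <- character()
  if (!is.null(flags))
    bad <- intersect(refs$ref, names(flags)[flags == "unresolved"])
  ## refs used on the primary path must be resolved; parallel
  ## (confirmatory/sub-state) gates with unresolved refs are skipped
  primary_refs <- unique(unlist(lapply(tree$nodes, function(n)
    if (!n$parallel) vapply(n$terms, `[[`, "", "ref"))))
  if (length(intersect(bad, primary_refs)))
    stop("tree has unresolved thresholds: ",
         paste(intersect(bad, primary_refs), collapse = ", "))
  skip_parallel <- vapply(tree$nodes, function(n)
    n$parallel && any(vapply(n$terms, `[[`, "", "ref") %in% bad), logical(1))
  if (any(skip_parallel))
    warning("skipping side gate(s) with unresolved thresholds: ",
            paste(vapply(tree$nodes[skip_parallel], `[[`, "", "name"),
                  collapse = ", "))
  mk <- marker_matrix(unmixed, panel)
  n <- nrow(mk)
  channel_values <- function(ch) {
    if (ch %in% colnames(mk)) return(mk[, ch])
    if (ch %in% c("FSC-A", "SSC-A", "FSC-H")) return(events$scatter[[ch]])
    if (ch == "FSC-ratio")
      return(events$scatter[["FSC-H"]] / events$scatter[["FSC-A"]])
    stop("unknown gating channel: ", ch)
  }
  nodenames <- vapply(tree$nodes, function(x) x$name, character(1))
  member <- matrix(FALSE, n, length(tree$nodes),
                   dimnames = list(NULL, nodenames))
  depth <- integer(length(tree$nodes)); names(depth) <- nodenames
  label <- rep(NA_character_, n)
  deepest <- rep(NA_character_, n)      # deepest non-parallel gate reached
  for (k in seq_along(tree$nodes)) {
    nd <- tree$nodes[[k]]
    if (skip_parallel[k]) {
      depth[k] <- depth[nd$parent] + 1L
      next
    }
    if (is.na(nd$parent)) {
      m <- rep(TRUE, n); depth[k] <- 0L
    } else {
      depth[k] <- depth[nd$parent] + 1L
      pm <- member[, nd$parent]
      tv <- lapply(nd$terms, function(t) {
        v <- channel_values(t$channel)
        thr <- tree$thresholds[[t$ref]]
        if (t$op == ">") v > thr else v < thr
      })
      tm <- if (nd$combine == "any") Reduce(`|`, tv) else Reduce(`&`, tv)
      m <- pm & tm
    }
    member[, k] <- m
    if (!nd$parallel) deepest[m] <- nd$name
    if (!is.na(nd$population) && isTRUE(nd$target)) label[m] <- nd$population
  }
  unlabelled <- is.na(label)
  label[unlabelled] <- paste0(deepest[unlabelled], "/unassigned")

  counts <- colSums(member)
  parents <- vapply(tree$nodes, function(x) x$parent, character(1))
  freq <- data.frame(
    gate = nodenames,
    population = vapply(tree$nodes, function(x) x$population, character(1)),
    parent = parents,
    count = as.integer(counts),
    freq_of_parent = ifelse(is.na(parents), 100,
                            100 * counts / pmax(counts[parents], 1)),
    parallel = vapply(tree$nodes, function(x) x$parallel, logical(1)),
    row.names = NULL)
  structure(list(labels = label, frequency = freq, membership = member),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("<gating_result> ", length(x$labels), " events, ",
      sum(!grepl("/unassigned$", x$labels)), " assigned to populations\n",
      sep = "")
  f <- x$frequency[!is.na(x$frequency$population) & !x$frequency$parallel, ]
  print(data.frame(population = f$population, count = f$count,
                   freq_of_parent = round(f$freq_of_parent, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Confusion summary of gating against ground truth
#'
#' @param truth,predicted equal-length label vectors.
#' @return An object of class `gating_recovery`: confusion matrix,
#'   per-population recall and precision, and overall accuracy.
#' @export
evaluate_recovery <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors have different lengths")
  if (!length(intersect(unique(truth), unique(predicted))))
    warning("truth and predicted label sets are disjoint")
  lev <- sort(union(unique(truth), unique(predicted)))
  cm <- table(factor(truth, lev), factor(predicted, lev))
  tl <- sort(unique(truth))
  recall <- vapply(tl, function(p) {
    tot <- sum(cm[p, ]); if (tot == 0) NA_real_ else cm[p, p] / tot
  }, numeric(1))
  precision <- vapply(tl, function(p) {
    tot <- sum(cm[, p]); if (tot == 0) NA_real_ else cm[p, p] / tot
  }, numeric(1))
  structure(list(confusion = cm,
                 recall = recall, precision = precision,
                 accuracy = mean(truth == predicted)),
            class = "gating_recovery")
}

#' @export
print.gating_recovery <- function(x, ...) {
  cat("<gating_recovery> overall accuracy ",
      format(x$accuracy, digits = 4), "\n", sep = "")
  print(round(data.frame(recall = x$recall, precision = x$precision), 3))
  invisible(x)
}

#' Serialize a gate tree to JSON (and back)
#'
#' @param tree a [gate_tree()].
#' @param path file path.
#' @return `write_gate_tree()` returns `path` invisibly;
#'   `read_gate_tree()` returns a [gate_tree()].
#' @export
write_gate_tree <- function(tree, path) {
  jsonlite::write_json(
    list(version = tree$version,
         thresholds = as.list(tree$thresholds),
         nodes = lapply(tree$nodes, function(n)
           list(name = n$name, parent = n$parent, combine = n$combine,
                population = n$population, target = n$target,
                parallel = n$parallel,
                terms = lapply(n$terms, function(t)
                  list(channel = t$channel, op = t$op, ref = t$ref))))),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_gate_tree
#' @export
read_gate_tree <- function(path) {
  x <- jsonlite::read_json(path)
  nodes <- lapply(x$nodes, function(n)
    gate_node(n$name, n$parent %||% NA_character_,
              terms = lapply(n$terms, function(t)
                gate_term(t$channel, t$op, t$ref)),
              combine = n$combine,
              population = n$population %||% NA_character_,
              target = isTRUE(n$target), parallel = isTRUE(n$parallel)))
  thr <- unlist(x$thresholds) %||% numeric()
  gate_tree(nodes, thresholds = thr, version = x$version %||% "v1")
}
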