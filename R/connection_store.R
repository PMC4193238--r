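#' Connection record
#'
#' One VP-local synapse as stored in the adaptive containers: a
#' thread-local target index (2 B semantics), a delay in steps and a
#' synapse-type id (packed 4 B semantics), a double weight and, for
#' plastic types, a double trace.
#'
#' @param target thread-local index of the target node (>= 1).
#' @param syn_id synapse-type id in `[0, 256)`.
#' @param delay_steps transmission delay in units of the step (>= 1).
#' @param weight synaptic weight.
#' @param trace optional synaptic trace variable (STDP).
#' @return object of class `connection_record`.
#' @export
connection_record <- function(target, syn_id = 0, delay_steps = 1,
                              weight = 1, trace = NULL) {
  if (delay_steps < 1) stop("delay_steps must be >= 1")
  pack_delay_type(delay_steps, syn_id)  # range validation
  structure(list(target = target, syn_id = syn_id,
                 delay_steps = delay_steps, weight = weight, trace = trace),
            class = "connection_record")
}

new_hom <- function(record, k_cutoff) {
  list(kind = "hom", syn_id = record$syn_id,
       storage = "fixed", records = list(record))
}

hom_append <- function(hom, record, k_cutoff) {
  hom$records <- c(hom$records, list(record))
  if (length(hom$records) > k_cutoff) hom$storage <- "growable"
  hom
}

#' Per-VP connection store with sparse presence table
#'
#' Models the 4g connection infrastructure of one virtual process: a
#' sparse presence table (one bit per source GID, organised in
#' equally-sized groups) pointing at adaptive per-source containers.
#' Containers holding up to `k_cutoff` synapses of one type use fixed-size
#' storage, longer type-homogeneous lists use growable storage, and
#' sources with several synapse types in local use get a heterogeneous
#' wrapper with one type-homogeneous child per type.
#'
#' @param n_sources number of source GIDs the table covers.
#' @param k_cutoff fixed-storage threshold (default 3).
#' @param group_size presence-table group size in GIDs (default 48,
#'   consistent with the 1/3 B per-neuron table overhead of the memory
#'   model: one bit plus 16 B group bookkeeping per 48 entries).
#' @return object of class `connection_store`.
#' @export
connection_store <- function(n_sources, k_cutoff = 3, group_size = 48) {
  if (n_sources < 1) stop("n_sources must be >= 1")
  structure(list(n_sources = n_sources, k_cutoff = k_cutoff,
                 group_size = group_size,
                 containers = vector("list", n_sources)),
            class = "connection_store")
}

#' Add one connection to a store
#'
#' Container selection: an unset presence bit creates a fixed container
#' of one record; further same-type adds grow the fixed container up to
#' `k_cutoff` records and then promote it to growable storage (records
#' copied in insertion order); an add with a new synapse type wraps the
#' existing container in a heterogeneous container whose children are
#' ordered by first appearance of each type.
#'
#' @param store a [connection_store()].
#' @param source_gid source index in `[1, n_sources]`.
#' @param record a [connection_record()].
#' @return the updated store.
#' @export
add_connection <- function(store, source_gid, record) {
  stopifnot(inherits(store, "connection_store"),
            inherits(record, "connection_record"))
  if (source_gid < 1 || source_gid > store$n_sources)
    stop("source_gid outside table range")
  k <- store$k_cutoff
  cont <- store$containers[[source_gid]]
  if (is.null(cont)) {
    cont <- new_hom(record, k)
  } else if (cont$kind == "hom") {
    if (cont$syn_id == record$syn_id) {
      cont <- hom_append(cont, record, k)
    } else {
      cont <- list(kind = "het",
                   children = list(cont, new_hom(record, k)))
    }
  } else {  # het
    ids <- vapply(cont$children, `[[`, numeric(1), "syn_id")
    i <- match(record$syn_id, ids)
    if (is.na(i)) {
      cont$children <- c(cont$children, list(new_hom(record, k)))
    } else {
      cont$children[[i]] <- hom_append(cont$children[[i]], record, k)
    }
  }
  store$containers[[source_gid]] <- cont
  store
}

#' Presence bits of a store
#'
#' @param store a [connection_store()].
#' @return logical vector of length `n_sources`; bit set iff an inner
#'   structure exists for that source.
#' @export
presence_bits <- function(store) {
  !vapply(store$containers, is.null, logical(1))
}

#' Deliver an event: enumerate a source's local records
#'
#' Yields every record stored for `source_gid` exactly once, visiting the
#' children of heterogeneous containers in their stored order, and
#' records within a type in insertion order.  An unset presence bit
#' yields an empty list.
#'
#' @param store a [connection_store()].
#' @param source_gid source index.
#' @return list of `connection_record`s (possibly empty).
#' @export
deliver <- function(store, source_gid) {
  stopifnot(inherits(store, "connection_store"))
  cont <- store$containers[[source_gid]]
  if (is.null(cont)) return(list())
  if (cont$kind == "hom") return(cont$records)
  do.call(c, lapply(cont$children, `[[`, "records"))
}

#' Container kind for each source
#'
#' @param store a [connection_store()].
#' @return character vector over sources: `"empty"`, `"fixed"`,
#'   `"growable"` or `"heterogeneous"`.
#' @export
container_kinds <- function(store) {
  vapply(store$containers, function(cont) {
    if (is.null(cont)) return("empty")
    if (cont$kind == "het") return("heterogeneous")
    cont$storage
  }, character(1))
}

#' Connection-creation handshake
#'
#' Before a synapse is created, the source node emits a test event of the
#' connection's event kind twice: once at the new synapse (via its
#' checking helper) and once at the target node.  Either leg rejects the
#' event kind it cannot handle (the simulator signals this by an
#' exception from the base-class handler); the connection is created only
#' if both legs accept.
#'
#' @param source_emits event kinds the source node emits (the kind under
#'   test is taken from this set; informative, not a gate).
#' @param synapse_handles event kinds the synapse type can transmit.
#' @param target_handles event kinds the target node can receive.
#' @param event_kind the kind of event the new connection would carry.
#' @return list with `ok` (logical) and, on rejection, `failed_leg`
#'   (`"synapse"` or `"target"`, the first leg that rejected).
#' @export
handshake <- function(source_emits, synapse_handles, target_handles,
                      event_kind) {
  if (!event_kind %in% synapse_handles)
    return(list(ok = FALSE, failed_leg = "synapse"))
  if (!event_kind %in% target_handles)
    return(list(ok = FALSE, failed_leg = "target"))
  list(ok = TRUE, failed_leg = NULL)
}

#' Byte accounting of a store
#'
#' Per-source infrastructure overhead (0 for empty lists, `m1_c` for
#' singletons, `mgt1_c` for longer lists) plus per-record object bytes
#' from the synapse catalog of the parameter set's generation.
#'
#' @param store a [connection_store()].
#' @param params a [memory_params()].
#' @param record_bytes named numeric, bytes per record keyed by syn_id
#'   (as character).  Defaults to syn_id 0 = static and 1 = STDP object
#'   sizes of the generation in `params`.
#' @return list with `per_source_overhead` (numeric vector),
#'   `overhead_total`, `object_total` and `total` (bytes).
#' @export
store_overhead_bytes <- function(store, params = memory_params("4g"),
                                 record_bytes = NULL) {
  stopifnot(inherits(store, "connection_store"),
            inherits(params, "memory_params"))
  if (is.null(record_bytes)) {
    record_bytes <- c(
      "0" = struct_layout(synapse_catalog(params$generation, "static"))$total_bytes,
      "1" = struct_layout(synapse_catalog(params$generation, "stdp"))$total_bytes)
  }
  lens <- vapply(seq_len(store$n_sources),
                 function(g) length(deliver(store, g)), numeric(1))
  per_source <- ifelse(lens == 0, params$mempty_c,
                       ifelse(lens == 1, params$m1_c, params$mgt1_c))
  obj <- 0
  for (g in which(lens > 0)) {
    ids <- vapply(deliver(store, g), `[[`, numeric(1), "syn_id")
    b <- record_bytes[as.character(ids)]
    if (anyNA(b)) stop("record_bytes missing an entry for a syn_id in use")
    obj <- obj + sum(b)
  }
  list(per_source_overhead = per_source,
       overhead_total = sum(per_source),
       object_total = obj,
       total = sum(per_source) + obj)
}

#' Store census: list-length histogram and container kinds
#'
#' @param store a [connection_store()].
#' @return list with `lengths` (per-source record counts), `n_empty`,
#'   `n_one`, `n_multi` and `kinds` (table of container kinds).
#' @export
store_census <- function(store) {
  lens <- vapply(seq_len(store$n_sources),
                 function(g) length(deliver(store, g)), numeric(1))
  list(lengths = lens,
       n_empty = sum(lens == 0),
       n_one = sum(lens == 1),
       n_multi = sum(lens > 1),
       kinds = table(container_kinds(store)))
}
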