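#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labelling of the active bins of a flattened grid.
// The neighbour structure is passed in compressed form: neighbours of bin i
// (0-based) are adj[offsets[i] .. offsets[i+1]-1]. Returns 1-based
// component labels (0 for inactive bins).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector active, IntegerVector adj,
                                   IntegerVector offsets) {
  const int n = active.size();
  IntegerVector labels(n, 0);
  std::vector<int> queue;
  queue.reserve(256);
  int comp = 0;
  for (int s = 0; s < n; ++s) {
    if (!active[s] || labels[s]) continue;
    ++comp;
    labels[s] = comp;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      const int v = queue.back();
      queue.pop_back();
      for (int j = offsets[v]; j < offsets[v + 1]; ++j) {
        const int u = adj[j];
        if (active[u] && !labels[u]) {
          labels[u] = comp;
          queue.push_back(u);
        }
      }
    }
  }
  return labels;
}
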