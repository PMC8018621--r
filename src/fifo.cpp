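#include <Rcpp.h>
using namespace Rcpp;

// Multi-server FIFO queue: patients are served in order of queue entry by
// `capacity` identical servers. entry must be non-decreasing. Returns the
// service start time of each patient; start[i] = max(entry[i], earliest
// server free time), and the chosen server becomes free at
// start[i] + service[i].
// [[Rcpp::export]]
NumericVector fifo_serve_cpp(NumericVector entry, NumericVector service,
                             int capacity) {
  const int n = entry.size();
  if (service.size() != n) stop("entry and service lengths differ");
  if (capacity < 1) stop("capacity must be >= 1");
  for (int i = 1; i < n; ++i) {
    if (entry[i] < entry[i - 1]) stop("entry times must be sorted (FIFO)");
  }
  NumericVector start(n);
  std::vector<double> free_at(capacity, 0.0);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 1; j < capacity; ++j) {
      if (free_at[j] < free_at[k]) k = j;
    }
    const double s = std::max(entry[i], free_at[k]);
    start[i] = s;
    free_at[k] = s + service[i];
  }
  return start;
}
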