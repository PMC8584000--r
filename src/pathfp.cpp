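// Hashed linear-path fingerprint.
//
// Enumerates all simple linear paths of 1..max_len bonds in the
// molecular graph, builds a direction-canonical label string for each
// (atom and bond labels supplied from R), hashes it with FNV-1a and
// sets two bits per path in an nbits-wide fingerprint.

#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

static inline uint32_t fnv1a(const std::string& s, uint32_t seed) {
  uint32_t h = 2166136261u ^ seed;
  for (unsigned char c : s) {
    h ^= c;
    h *= 16777619u;
  }
  return h;
}

struct PathEnum {
  const std::vector<std::string>& alab;
  const std::vector<std::string>& blab;
  const std::vector<std::vector<std::pair<int, int> > >& adj;  // (nbr, bond)
  int max_len;
  int nbits;
  std::set<int>& bits;
  std::vector<int> atoms;
  std::vector<int> bonds;
  std::vector<char> visited;
  long budget;  // hard cap on enumerated paths

  void emit() {
    std::string fwd, rev;
    size_t na = atoms.size();
    for (size_t k = 0; k < na; ++k) {
      fwd += alab[atoms[k]];
      if (k + 1 < na) fwd += blab[bonds[k]];
    }
    for (size_t k = na; k-- > 0;) {
      rev += alab[atoms[k]];
      if (k > 0) rev += blab[bonds[k - 1]];
    }
    const std::string& canon = (fwd <= rev) ? fwd : rev;
    bits.insert((int)(fnv1a(canon, 0u) % (uint32_t)nbits));
    bits.insert((int)(fnv1a(canon, 0x9e3779b9u) % (uint32_t)nbits));
  }

  void extend(int atom) {
    if (budget-- <= 0) return;
    for (const auto& nb : adj[atom]) {
      if (visited[nb.first]) continue;
      atoms.push_back(nb.first);
      bonds.push_back(nb.second);
      visited[nb.first] = 1;
      emit();
      if ((int)bonds.size() < max_len) extend(nb.first);
      visited[nb.first] = 0;
      atoms.pop_back();
      bonds.pop_back();
    }
  }
};

// [[Rcpp::export]]
IntegerVector pathfp_bits(CharacterVector atom_labels, IntegerVector bond_a,
                          IntegerVector bond_b, CharacterVector bond_labels,
                          int nbits, int max_len) {
  int n = atom_labels.size();
  int m = bond_a.size();
  std::vector<std::string> alab(n), blab(m);
  for (int i = 0; i < n; ++i) alab[i] = as<std::string>(atom_labels[i]);
  for (int k = 0; k < m; ++k) blab[k] = as<std::string>(bond_labels[k]);
  std::vector<std::vector<std::pair<int, int> > > adj(n);
  for (int k = 0; k < m; ++k) {
    int i = bond_a[k] - 1, j = bond_b[k] - 1;
    adj[i].push_back(std::make_pair(j, k));
    adj[j].push_back(std::make_pair(i, k));
  }
  std::set<int> bits;
  PathEnum pe{alab, blab, adj, max_len, nbits, bits,
              std::vector<int>(), std::vector<int>(),
              std::vector<char>(n, 0), 500000L};
  for (int s = 0; s < n; ++s) {
    pe.atoms.assign(1, s);
    pe.bonds.clear();
    std::fill(pe.visited.begin(), pe.visited.end(), 0);
    pe.visited[s] = 1;
    pe.extend(s);
  }
  return IntegerVector(bits.begin(), bits.end());
}
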