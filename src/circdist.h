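#ifndef PHASETE_CIRCDIST_H
#define PHASETE_CIRCDIST_H

#include <cmath>

// wrapped absolute difference between two angles (radians), in [0, pi];
// wrapped inputs give |x - y| <= 2*pi, so reduction is a subtraction loop
static inline double circ_adiff(double x, double y) {
  double d = std::fabs(x - y);
  while (d > 2.0 * M_PI) d -= 2.0 * M_PI;
  return d > M_PI ? 2.0 * M_PI - d : d;
}

#endif
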