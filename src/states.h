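#ifndef EXONSTATE_STATES_H
#define EXONSTATE_STATES_H

// Fixed 15-state gene-structure alphabet (0-based, order shared with R side):
// IR, I0, I1, I2, E0, E1, E2, ASS0, ASS1, ASS2, DSS0, DSS1, DSS2, START, STOP
namespace exonstate {

enum State {
  IR = 0, I0, I1, I2, E0, E1, E2,
  ASS0, ASS1, ASS2, DSS0, DSS1, DSS2, START, STOP
};

const int N_STATES = 15;
const int N_EDGES = 23;

// 23 directed transition edges. Frame convention: the index on a state is the
// codon position (0-based) of the base carrying it; intron frame equals the
// codon position of the next coding base, hence DSS_i feeds I_{(i+1) mod 3}.
const int EDGE_FROM[N_EDGES] = {
  IR, IR, START,
  E0, E1, E2,
  E2, E0, E1,
  DSS0, DSS1, DSS2,
  I0, I1, I2,
  I0, I1, I2,
  ASS0, ASS1, ASS2,
  E1, STOP
};
const int EDGE_TO[N_EDGES] = {
  IR, START, E1,
  E1, E2, E0,
  DSS0, DSS1, DSS2,
  I1, I2, I0,
  I0, I1, I2,
  ASS0, ASS1, ASS2,
  E1, E2, E0,
  STOP, IR
};

}  // namespace exonstate

#endif
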