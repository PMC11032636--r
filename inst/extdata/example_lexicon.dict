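;;; Small example pronunciation lexicon in CMUdict dialect (ARPAbet with
;;; stress digits). Hand-assembled for examples and documentation; not an
;;; excerpt of any published dictionary.
TALL  T AO1 L
TEENSY  T IY1 N Z IY0
TINY  T AY1 N IY0
HUGE  HH Y UW1 JH
SMALL  S M AO1 L
BIG  B IH1 G
MITE  M AY1 T
WHALE  W EY1 L
ELEPHANT  EH1 L AH0 F AH0 N T
MOUSE  M AW1 S
GIGANTIC  JH AY0 G AE1 N T IH0 K
MINIATURE  M IH1 N IY0 AH0 CH ER0
BALLOON  B AH0 L UW1 N
PEBBLE  P EH1 B AH0 L
MOUNTAIN  M AW1 N T AH0 N
THIMBLE  TH IH1 M B AH0 L
OCEAN  OW1 SH AH0 N
CRUMB  K R AH1 M
TOWER  T AW1 ER0
SEED  S IY1 D
CATHEDRAL  K AH0 TH IY1 D R AH0 L
BUTTON  B AH1 T AH0 N
GLACIER  G L EY1 SH ER0
NEEDLE  N IY1 D AH0 L
FREIGHTER  F R EY1 T ER0
PETAL  P EH1 T AH0 L
CANYON  K AE1 N Y AH0 N
GRAIN  G R EY1 N
STADIUM  S T EY1 D IY0 AH0 M
BEAD  B IY1 D
AVALANCHE  AE1 V AH0 L AE2 N CH
SPECK  S P EH1 K
COLOSSUS  K AH0 L AA1 S AH0 S
MIDGE  M IH1 JH
ZEPPELIN  Z EH1 P AH0 L IH0 N
DOT  D AA1 T
WAREHOUSE  W EH1 R HH AW2 S
ATOM  AE1 T AH0 M
CONTINENT  K AA1 N T AH0 N AH0 N T
FLEA  F L IY1
VOLCANO  V AA0 L K EY1 N OW0
INCH  IH1 N CH
LIMOUSINE  L IH1 M AH0 Z IY2 N
PIN  P IH1 N
SKYSCRAPER  S K AY1 S K R EY2 P ER0
DUST  D AH1 S T
HIPPOPOTAMUS  HH IH2 P AH0 P AA1 T AH0 M AH0 S
THE  DH AH0
OF  AH1 V
QUICKLY  K W IH1 K L IY0
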