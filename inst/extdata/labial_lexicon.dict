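;;; Small ARPABET pronunciation lexicon (CMU dictionary dialect) covering the
;;; one-word-utterance vocabulary and the synthetic generator's first words.
;;; Stress digits are informational; the coder strips them.
;;; MMHMM has no conventional dictionary entry; the entry below is an
;;; artifact convention (onset /m/ decides the label either way).
ABSOLUTELY  AE2 B S AH0 L UW1 T L IY0
ACTUALLY  AE1 K CH UW0 AH0 L IY0
ALRIGHT  AO2 L R AY1 T
AND  AH0 N D
ANYWAY  EH1 N IY0 W EY2
BECAUSE  B IH0 K AH1 Z
BUT  B AH1 T
DEFINITELY  D EH1 F AH0 N AH0 T L IY0
DO  D UW1
EXACTLY  IH0 G Z AE1 K T L IY0
EXCELLENT  EH1 K S AH0 L AH0 N T
GOOD  G UH1 D
HE  HH IY1
HMM  HH AH1 M
HOW  HH AW1
I  AY1
I'LL  AY1 L
I'M  AY1 M
IT  IH1 T
MAYBE  M EY1 B IY0
MMHMM  M AH0 HH M
NEXT  N EH1 K S T
NICE  N AY1 S
NO  N OW1
NOW  N AW1
OH  OW1
OK  OW2 K EY1
OKAY  OW2 K EY1
PERHAPS  P ER0 HH AE1 P S
PROBABLY  P R AA1 B AH0 B L IY0
REALLY  R IH1 L IY0
RIGHT  R AY1 T
SHE  SH IY1
SO  S OW1
SURE  SH UH1 R
THANKS  TH AE1 NG K S
THAT  DH AE1 T
THAT'S  DH AE1 T S
THE  DH AH0
THEN  DH EH1 N
THERE  DH EH1 R
THEY  DH EY1
THIS  DH IH1 S
VERY  V EH1 R IY0
WE  W IY1
WELL  W EH1 L
WHAT  W AH1 T
WHEN  W EH1 N
WHERE  W EH1 R
WHICH  W IH1 CH
WHO  HH UW1
WHY  W AY1
YEAH  Y AE1
YEP  Y EH1 P
YES  Y EH1 S
YOU  Y UW1
SLEEP  S L IY1 P
SPIN  S P IH1 N
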