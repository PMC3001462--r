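refpos
690
694
695
700
705
706
708
709
711
714
731
733
735
736
738
739
741
764
768
784
791
794
797
802
810
816
817
848
861
904
938
941
942
973
976
984
994
997
1001
1012
1014
1016
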