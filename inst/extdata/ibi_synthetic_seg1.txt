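# synthetic interbeat-interval series, segment 1: one interval in ms per line
804.27
823.91
839.83
845.52
837.93
829.77
831.87
788.73
839.81
863.32
796.06
808.37
840.91
813.73
818.92
826.53
833.13
837.39
824.02
865.03
802.19
862.36
796.92
819.07
828.23
854.06
804.47
794.18
811.05
784.88
819.01
799.46
832.32
822.52
785.53
808.65
838.06
844.44
833.09
802.95
809.45
826.35
819.91
851.64
846.28
817.64
821.61
819.61
803.66
833.89
816.12
816.88
824.43
826.04
847.10
792.51
787.44
848.24
821.91
826.18
837.46
837.80
849.76
830.00
813.25
847.19
836.21
848.23
863.47
802.27
786.54
810.75
812.87
834.77
823.34
852.67
820.66
799.56
807.48
831.45
856.46
818.85
814.91
777.10
822.18
846.03
802.32
799.34
809.27
813.45
853.10
799.16
821.60
833.92
849.92
820.02
848.34
797.99
831.25
846.49
821.44
843.67
778.19
833.29
816.31
816.21
835.58
831.13
819.62
814.85
816.79
778.62
828.90
806.20
835.48
814.76
820.40
827.95
858.95
838.89
822.07
799.24
837.61
809.00
826.83
831.03
822.75
818.07
831.24
821.03
791.15
837.28
816.48
813.18
827.58
788.28
844.04
831.64
808.24
801.34
844.98
825.29
845.94
802.93
834.13
821.84
803.55
835.46
819.64
812.61
833.75
794.98
827.49
809.43
803.91
790.71
815.03
824.01
816.51
803.92
817.68
845.23
796.32
802.76
828.60
811.57
826.38
824.48
797.12
813.65
798.78
800.26
837.10
824.77
808.29
783.83
813.28
851.89
806.85
808.80
814.14
821.51
816.61
835.24
848.68
783.35
835.21
847.51
788.78
820.84
885.85
809.67
833.31
804.78
821.65
850.35
815.93
838.22
804.14
828.83
805.13
808.78
833.85
807.38
814.60
863.65
834.36
841.78
801.23
834.20
788.47
825.73
799.13
794.86
815.70
811.74
787.06
839.34
814.66
831.57
861.72
809.70
843.76
832.71
846.78
799.00
805.25
801.47
803.31
811.36
829.36
841.56
823.30
788.50
841.59
812.93
844.16
841.12
827.09
797.01
835.90
823.92
818.57
823.54
840.56
849.50
817.71
791.93
801.14
785.58
802.38
812.92
804.05
796.54
843.54
868.26
807.12
795.02
865.01
824.69
776.15
821.83
822.39
801.24
806.55
808.27
818.62
811.95
807.10
807.77
817.95
770.94
848.33
827.55
851.62
822.55
810.01
834.84
788.32
814.00
822.17
827.57
818.47
810.82
842.89
809.88
830.07
848.18
775.63
815.08
789.62
800.18
839.88
817.48
872.25
821.88
831.03
844.82
825.64
793.59
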