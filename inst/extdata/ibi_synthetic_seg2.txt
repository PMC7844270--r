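# synthetic interbeat-interval series, segment 2: one interval in ms per line
843.27
810.42
826.16
830.74
826.86
818.20
845.65
818.39
854.25
818.94
842.14
858.81
796.43
815.27
817.74
830.79
815.18
774.92
778.58
842.40
814.80
789.77
817.08
840.61
852.16
812.69
815.63
790.08
827.81
809.14
827.73
831.96
837.57
809.67
828.57
790.86
806.69
805.56
779.03
820.61
823.50
813.87
832.87
807.67
796.78
827.35
806.23
844.51
812.68
831.13
825.46
806.70
846.74
830.91
821.52
824.69
831.53
821.52
769.21
824.83
813.77
823.14
829.87
843.75
807.66
842.10
825.70
837.62
835.63
832.23
802.30
818.47
830.58
803.82
810.79
829.86
833.04
827.87
804.97
801.34
845.67
824.38
821.50
817.95
799.73
830.39
816.32
816.90
835.84
833.95
843.62
811.92
831.04
843.61
801.15
805.39
800.79
795.24
821.36
831.09
840.38
837.73
802.97
851.37
808.68
821.79
812.83
817.92
823.19
822.02
819.57
821.83
811.76
811.44
791.81
813.51
811.30
865.85
796.88
822.33
794.65
795.05
822.12
803.09
819.97
812.73
809.59
785.64
799.22
823.05
829.63
811.64
820.00
839.06
844.44
801.38
818.01
840.39
812.03
819.11
818.54
804.94
812.45
819.50
812.98
838.89
811.84
812.65
831.83
802.07
819.31
793.67
839.81
815.36
812.06
798.99
819.87
806.42
810.95
841.85
817.02
801.81
822.77
813.84
830.01
844.31
803.15
827.72
821.44
835.20
816.10
834.20
790.39
848.67
834.68
817.44
795.41
830.91
828.20
819.89
822.57
810.09
826.26
825.00
815.26
797.32
831.89
829.41
805.81
792.94
823.48
814.14
824.29
798.04
803.72
838.43
826.85
829.95
850.81
822.19
786.04
825.66
839.88
854.95
796.63
800.47
808.02
802.11
809.04
816.85
799.61
854.57
821.83
818.57
828.41
820.63
817.76
845.06
816.32
798.22
826.55
814.03
811.14
801.87
827.27
817.05
828.75
816.02
808.82
841.22
815.39
836.09
799.61
812.09
815.43
813.37
842.89
819.61
824.14
804.01
807.62
836.94
841.36
841.19
796.57
854.79
837.26
819.55
831.94
803.52
801.40
820.83
799.66
823.22
842.02
802.45
807.47
820.79
802.73
813.50
834.81
836.45
826.51
788.58
819.08
838.07
833.80
816.76
774.18
821.03
829.74
820.78
822.67
827.32
813.27
842.23
827.98
798.91
843.45
840.44
833.98
791.78
810.34
830.79
820.74
825.91
861.74
806.11
784.14
824.64
808.33
827.57
806.21
857.54
817.90
811.90
817.18
834.64
821.65
792.41
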