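"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,26.17,27.21,26.5,31.12,35.35,40.68,46.69,50.51,57.55,65.74,71.52,76.59,81.65,86.17,86.56,90.28,91.79,32.01,36.03,40.92,46.08,49.48,68.6,71.09,77.11,80.7,86.97,57.23,58.61,58.98,58.37,50.53,53.77,59.5,63.34,67.07,47.57,42.29,36.35,34.12,36.12,42.68,83.37,79.53,72.8,70.71,74.92,77.99,70.52,68.75,65.52,57.75,51.2,46.34,44.6,43.73,49.93,56.85,66.1,71.68,66.85,64.92,57.97,50.28,48.01,54.15,57.89,65.56,46.21,57.58,65.27,72.29,77.41,82.41,85.8,89.85,88.7,90.25,88.38,82.87,79.71,72.87,64.75,58.25,51.59,29.15,29.4,28.92,28.86,33.45,31.24,29.18,30.1,28.41,31.42,37.06,43.28,49.5,54.48,56.66,57.94,58.95,59.49,55.46,38.5,37.45,36.51,38.71,40.18,39.53,37.69,34.19,36.43,38.09,40.83,42.83,71.98,65.27,65.49,64.84,66.23,68.53,72.45,75.82,78.97,80.96,79.85,74.13,72.53,67.56,69.63,69.9,72.06,74.31,77.38,74.83
2,26.81,28.43,27.51,29.95,35.02,42.32,45.26,52.85,58.47,62.75,71.53,77.8,82.43,87.31,89.73,90.92,92.37,30.94,36.77,41.08,46.23,50.06,67.88,71.3,78.34,82.48,86.95,57.13,60.77,61.48,60.66,52.68,53.7,58.72,62.99,67.5,48.93,44.5,38.53,34.17,37.43,42.6,85.87,80.25,73.15,73.08,74.44,78.79,70.66,70.72,65.65,58.5,51.39,45.74,43.77,45.1,51.57,60.12,68.09,71.13,68.91,64.98,60.54,52.12,48.84,54.54,58.27,64.37,49.89,58.87,66.05,75.33,79.61,85.94,88.37,90.79,90.83,89.11,89.31,84.84,79.86,73.2,67.2,59.36,52.15,35.19,29.83,30.01,31.69,32.02,33.24,32.03,29.97,30.26,32.29,38.95,46.09,51.72,55.38,58.87,58.84,62.51,60.77,58.86,39.9,39.45,39.06,39.69,42.33,42.89,41.14,37.42,38.65,40.95,42.73,43.14,73.54,70.46,68.7,65.06,66.53,68.66,73.77,78.56,81.08,81.92,79.88,75.36,73.04,70.43,72.32,71.25,72.35,76.3,78.68,76.15
3,22.5,25.88,26.09,29.12,33.33,36.83,41.02,49.9,55.15,63.95,68,76.43,78.73,83.79,85.56,89.64,87.89,29.38,34.8,38.84,43.53,46.95,68.06,68.42,76.13,77.34,83.31,55.16,55.37,55.97,56.33,47.9,51.16,54.2,59.89,62.4,44.4,42.05,34.49,32.1,33.31,41.56,81.82,78.92,70.75,71.27,70.72,78.74,67.33,68.59,62.62,55.15,46.3,44.66,40.56,42.3,49.41,57.25,62.87,70.43,65.82,62.01,54.82,49.19,47.24,50.09,55.08,61.51,47.77,57.5,65.85,71.44,78.57,81.87,85.12,87.41,89.04,88.26,87.33,81.55,78.14,71.98,65.77,57.62,50.36,32.72,27.67,28.35,29.05,31.13,30.57,30.62,28.39,28.18,29.75,39.45,43.22,48.42,53.97,57.22,59.4,57.78,58.24,57.69,38.31,38.52,37.87,38.14,39.76,39.9,40.18,35.99,37.06,38.67,41.52,40.52,73.79,68.09,67.97,65.1,64.08,67.51,72.93,75.31,77.77,78.74,77.48,76.6,72.47,68.81,69.66,68.95,71.91,74.62,76,73.38
4,23.37,24.55,25.59,28.67,35.1,36.38,44.32,50.3,55.56,64.21,69.71,73.7,79.66,83.68,86.32,89.16,88.85,28.28,35.77,37.69,43.34,47.74,65.86,69.39,75.74,77.88,83.6,55.19,57.98,58.1,55.9,47.6,51.64,57.12,60.54,66.16,43.95,42.92,35.49,30.11,36.69,41.08,83.14,77.54,70.86,67.72,72.4,78.59,68.71,69.09,65.67,57.46,48.4,44.74,43.11,43.08,48.37,56.25,65.89,67.76,65.48,63.77,54.71,48.74,46.55,51.77,55.92,62.02,52.68,58.21,68.12,72.35,78.47,85.33,88.16,90.37,90.15,90.61,87.95,84.71,80.43,72.06,64.27,59.1,50.48,31.61,30.26,30.65,28.65,30.92,31.91,30.9,29.96,29.4,32.73,39,44.89,48.19,56.09,61.34,57.63,59.51,60.49,57.63,39.39,36.56,37.91,39.38,42.83,40.7,40.01,36.71,37.2,39.78,42.09,40.77,74.49,69.5,68.55,65.42,65.29,69.04,72.4,76.28,79.43,83.58,79.73,75.74,72.28,70.83,69.76,70.68,73.78,72.45,76.14,75.11
5,22.69,24.59,26.11,24.89,33.65,36.86,42.76,50.34,56.22,61.35,70.78,74.39,80.82,84.14,84.5,88.32,88.4,30.14,33.94,36.72,43.29,47.94,65.1,69.61,74.69,78.08,83.54,55.84,56.9,57.75,55.14,47.58,52.83,56.96,60.29,63.99,45.59,42.51,32.95,30.58,33.66,40.52,79.5,77.17,69.89,67.52,70.29,77.45,68.01,69.33,61.79,56.46,47.05,43.24,41.14,41.52,48.1,56.17,65.12,67.59,65.06,63.75,54.52,47.71,45.03,51.08,54.63,61.27,49.91,58.17,66.3,72.96,76.58,83.73,87.97,91.66,90.68,89.52,87.62,84.29,78.09,72.28,66.36,58.22,53.22,30.29,29.11,30.38,32.13,32.36,32.5,31.03,30.24,30.2,32.4,39.42,44.39,48.89,54.49,57.95,59.65,59.75,60.37,57.41,39.58,36.06,38.51,39.86,41.36,39.68,37.9,37.95,35.48,38.88,42.83,41.7,73.7,69.48,66.29,66.61,66.2,68.75,75.52,77.26,79.51,82.85,80.57,77.11,72.76,68.31,69.42,71.05,72.36,76.29,76.78,74.73
6,22.59,26.23,24.64,27.64,32.84,39.69,42.23,50.18,55.93,62.73,67.65,72.17,78.58,83.65,85.88,86.38,89.75,28.81,33.51,38.18,40.41,46.86,65.54,70.46,75.3,78.49,84.3,55.09,55.33,54.93,58.57,51.06,50.49,55.85,60.16,63.11,44.14,40.7,35.01,29.29,34.42,37.25,80.99,75.49,69.21,66.89,73.09,75.77,70,69.09,64.03,55.29,46.24,42.62,38.54,41.27,48.47,57.72,63.36,68.28,64.41,61.88,55.29,47.95,45.62,49.03,54.75,62.79,50.83,59.36,65.17,73.77,77.32,83.96,85.49,90.6,91.61,88.67,88.38,83.95,79.67,73.72,66.81,59.25,50.6,33.43,28.25,30.88,31.4,32.16,31.73,31.39,27.34,31.41,32.19,38.7,44.24,49.27,56.37,58.38,59,58.39,60.16,58.97,39.86,37.69,37.54,37.84,41.15,39.88,39.94,36.14,38.18,38.89,41.62,41.23,72.72,69.75,67.09,65.82,65.82,71.28,75.51,76.78,81.79,80.46,79.74,77.38,71.6,70.41,69.25,69.45,72.95,75.33,76.87,72.85
7,22.75,23.09,22.53,26,31.45,36.68,41.07,47.5,54.41,62.67,67.17,73.83,78.67,83.89,85.01,88.17,89.1,27.9,32.49,36.19,43.29,46.77,63.77,69.83,74.48,76.44,82.17,52.68,55.06,54.85,55.93,47.93,51.35,56.3,60.14,62.65,44.24,39.43,33.84,31.11,32.51,39.7,79.47,76.35,68.36,68.01,70.6,75.86,68.76,66.49,61.18,54.71,47.21,42.91,41.09,41.43,47.57,54.69,62.43,67.27,64.75,61.85,55.66,49.5,44.86,52.06,53.82,58.2,48.69,56.63,64.55,72.68,77.95,81.34,86.49,88.54,87.39,88.51,87.22,83.34,80.46,71.45,63.94,59.92,50.97,31.78,29.57,28.92,30.34,28.89,32.15,32.73,27.61,29.39,29.49,38.79,45.08,49.47,53.79,58.13,59.79,58.92,59.88,57.9,38.28,37.7,37.75,36.67,40.79,37.42,40.11,35.66,35.29,37.9,41.56,40.07,68.27,64.71,62.64,61.45,62.79,65.72,69.18,73.22,76.71,78.92,78.49,70.05,69.41,67.36,67.13,67.16,71.44,72.76,73.65,71.19
8,19.5,20.7,21.74,24.36,28.32,34.86,38.32,45.03,53.26,60.77,66.5,73.04,75.68,80.01,82.8,85.68,87.85,27.72,30.67,33.49,39.37,46.4,61.18,65.39,73.78,76.36,80.28,51.98,51.21,53.87,51.9,44.2,48.74,53.48,59.12,60.7,41.52,37,33.11,29.05,31.64,37.14,79.7,75.19,67.1,65.61,68.44,75.31,66.22,64.22,62.29,52.96,46.25,39.92,39.32,39.34,47.69,51.81,62.28,65.58,62.62,60.47,54.15,45.75,42.29,46.67,52.03,56.95,51.76,59.5,68.2,76.48,79.56,85.92,88.06,91.91,90.77,92.26,90.58,84.95,82.05,72.69,66.42,62.55,51.98,34.32,31.88,33.05,30.61,32.33,32.52,31.66,31.8,31.42,32.59,42.43,46.6,51.58,58.16,60.76,61.78,62.17,59.98,60.75,40.6,39.72,40.1,41.36,45.83,43.88,42.48,40.13,37.3,41.01,44.4,43.54,75.12,70.82,69.98,66.43,65.69,69.79,75.51,78.15,81.06,83.8,82.47,75.83,76.13,71.5,71.41,73.05,74.17,77.57,79.46,77
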